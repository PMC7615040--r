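# Signed-interaction Bayesian network over suitability rasters: per-cell
# condensation of functional groups, OR/AND trigger resolution of a star of
# parents around a focal node, and chaining of sub-networks (indirect
# interactions) as priors.
#
# Per cell, with prior occurrence probability p and parent probabilities
# q_j (split by edge sign), each direction fires with trigger probability
#   OR:  T = 1 - prod_j (1 - q_j)      (any one interactor suffices)
#   AND: T = prod_j q_j                (all interactors must co-occur)
# and an empty direction never fires (T = 0). The posterior has exactly
# three states - increased, decreased, no change:
#   posterior = T+ (1-T-) p+  +  (1-T+) T- p-  +  [T+ T- + (1-T+)(1-T-)] p
# with p+ = p + alpha (1-p) and p- = p (1-alpha); simultaneous positive and
# negative triggers cancel to "no change". The product formulas are the
# closed form of the 2^n enumeration over parent presence/absence outcomes
# (see enumerate_posterior), so resolution is linear, not exponential, in
# the number of parents.

#' Resolution settings for the interaction network
#'
#' @param method `"OR"` (any one interactor triggers an effect) or `"AND"`
#'   (all interactors of a direction must co-occur).
#' @param alpha interaction strength in \[0, 1\]: the fraction by which a
#'   triggered effect pushes the prior towards 1 (positive) or 0
#'   (negative). `alpha = 0` leaves every prior unchanged.
#' @return a `resolution_config` list.
#' @export
resolution_config <- function(method = c("OR", "AND"), alpha = 0.5) {
  method <- match.arg(toupper(method[1]), c("OR", "AND"))
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(method = method, alpha = alpha),
            class = "resolution_config")
}

#' Define a signed interaction network
#'
#' A set of star-shaped resolution steps: optional sub-networks (resolved
#' first, in order, each substituting its focal's posterior for its prior)
#' followed by the main star around the focal species.
#'
#' @param edges data.frame with columns `parent`, `child`,
#'   `sign` (`"+"`/`"-"`) and optional `subnetwork_order` (0 or `NA` for the
#'   main network, 1, 2, ... for sub-networks resolved in that order).
#' @param focal focal species label (child of the main network).
#' @return an `interaction_network`.
#' @export
interaction_network <- function(edges, focal) {
  if (nrow(edges) == 0) {
    edges <- data.frame(parent = character(0), child = character(0),
                        sign = character(0), subnetwork_order = integer(0))
  }
  stopifnot(all(c("parent", "child", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c("+", "-"))) {
    stop("edge signs must be '+' or '-'", call. = FALSE)
  }
  if (is.null(edges$subnetwork_order)) edges$subnetwork_order <- 0L
  edges$subnetwork_order[is.na(edges$subnetwork_order)] <- 0L
  main_children <- unique(edges$child[edges$subnetwork_order == 0L])
  if (length(main_children) > 1 ||
      (length(main_children) == 1 && main_children != focal)) {
    stop("main-network edges must all point at the focal species",
         call. = FALSE)
  }
  sub_orders <- sort(unique(edges$subnetwork_order[edges$subnetwork_order > 0]))
  sub_focals <- vapply(sub_orders, function(o) {
    ch <- unique(edges$child[edges$subnetwork_order == o])
    if (length(ch) != 1) {
      stop("each sub-network step must have exactly one child", call. = FALSE)
    }
    ch
  }, character(1))
  # no node may be consumed as a parent before the step that resolves it
  for (i in seq_along(sub_orders)) {
    earlier <- edges$subnetwork_order < sub_orders[i]
    if (sub_focals[i] %in% edges$parent[earlier & edges$subnetwork_order > 0]) {
      stop("cyclic step ordering: '", sub_focals[i],
           "' used as a parent before it is resolved", call. = FALSE)
    }
  }
  if (focal %in% edges$parent) {
    stop("focal species cannot be a parent", call. = FALSE)
  }
  structure(list(edges = edges, focal = focal, sub_orders = sub_orders,
                 sub_focals = sub_focals),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> focal '%s', %d edges, %d sub-network(s)\n",
              x$focal, nrow(x$edges), length(x$sub_orders)))
  invisible(x)
}

#' Condense a functional group to its top-k per-cell suitabilities
#'
#' Reduces many same-role interactor rasters (e.g. all predatory birds) to
#' `k` rasters holding, cell by cell, the k largest suitabilities across
#' the group. Species identity may differ from cell to cell; only the
#' interaction direction matters downstream.
#'
#' @param rasters list of >= k aligned [suitability_raster]s.
#' @param k how many per-cell order statistics to keep (default 3).
#' @return list of `k` suitability rasters (rank 1 = per-cell maximum).
#' @export
condense_top_k <- function(rasters, k = 3) {
  if (length(rasters) < k) {
    stop(sprintf("need at least k = %d rasters, got %d", k, length(rasters)),
         call. = FALSE)
  }
  for (r in rasters[-1]) stop_if_misaligned(rasters[[1]], r)
  g <- rasters[[1]]
  stack <- vapply(rasters, function(r) as.vector(r$values),
                  numeric(g$n_rows * g$n_cols))
  topk <- apply(stack, 1, function(v) sort(v, decreasing = TRUE)[seq_len(k)])
  if (k == 1) topk <- matrix(topk, nrow = 1)
  lapply(seq_len(k), function(i) {
    suitability_raster(g, matrix(topk[i, ], g$n_rows, g$n_cols),
                       species_id = sprintf("group_rank_%d", i),
                       source = "condensed", scenario_tag = g$scenario_tag)
  })
}

trigger_prob <- function(q_list, method) {
  if (!length(q_list)) return(0)   # empty direction never fires
  if (method == "OR") {
    acc <- 1
    for (q in q_list) acc <- acc * (1 - q)
    1 - acc
  } else {
    acc <- 1
    for (q in q_list) acc <- acc * q
    acc
  }
}

#' Resolve a star of signed parents over a prior raster
#'
#' Applies the three-state posterior update cell-wise (see the formulas at
#' the top of this file's source).
#'
#' @param prior a [suitability_raster] (the focal node's SDM output).
#' @param parents list of `(raster, sign)` pairs: each element a list with
#'   `raster` (a [suitability_raster] aligned to `prior`) and `sign`
#'   (`"+"` or `"-"`).
#' @param cfg a [resolution_config].
#' @return the posterior [suitability_raster] (`source = "posterior"`).
#' @export
resolve <- function(prior, parents = list(), cfg = resolution_config()) {
  stopifnot(inherits(prior, "suitability_raster"),
            inherits(cfg, "resolution_config"))
  q_pos <- list(); q_neg <- list()
  for (pa in parents) {
    stop_if_misaligned(prior, pa$raster)
    v <- pa$raster$values
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE)) {
      stop("parent probabilities outside [0,1]", call. = FALSE)
    }
    if (pa$sign == "+") q_pos <- c(q_pos, list(v))
    else if (pa$sign == "-") q_neg <- c(q_neg, list(v))
    else stop("parent sign must be '+' or '-'", call. = FALSE)
  }
  p <- prior$values
  t_pos <- trigger_prob(q_pos, cfg$method)
  t_neg <- trigger_prob(q_neg, cfg$method)
  p_up <- p + cfg$alpha * (1 - p)
  p_dn <- p * (1 - cfg$alpha)
  post <- t_pos * (1 - t_neg) * p_up +
    (1 - t_pos) * t_neg * p_dn +
    (t_pos * t_neg + (1 - t_pos) * (1 - t_neg)) * p
  suitability_raster(prior, post, species_id = prior$species_id,
                     source = "posterior", scenario_tag = prior$scenario_tag)
}

#' Resolve a chained network of sub-networks and the main star
#'
#' Sub-networks are resolved in their stated order, each sub-focal's
#' posterior replacing its prior, so indirect interactions (e.g. a
#' competitor suppressing a food plant that supports the focal species)
#' propagate without inflating the main star's parent count. The main star
#' around the focal species is resolved last.
#'
#' @param network an [interaction_network].
#' @param priors named list mapping every node referenced by an edge (and
#'   the focal) to its prior [suitability_raster].
#' @param cfg a [resolution_config].
#' @return the focal species' posterior [suitability_raster].
#' @export
resolve_chain <- function(network, priors, cfg = resolution_config()) {
  stopifnot(inherits(network, "interaction_network"))
  needed <- unique(c(network$edges$parent, network$edges$child, network$focal))
  missing <- setdiff(needed, names(priors))
  if (length(missing)) {
    stop("missing prior raster(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  star <- function(child, sub) {
    e <- network$edges[network$edges$subnetwork_order == sub &
                         network$edges$child == child, , drop = FALSE]
    parents <- lapply(seq_len(nrow(e)), function(i) {
      list(raster = priors[[e$parent[i]]], sign = e$sign[i])
    })
    resolve(priors[[child]], parents, cfg)
  }
  for (i in seq_along(network$sub_orders)) {
    sf <- network$sub_focals[i]
    priors[[sf]] <- star(sf, network$sub_orders[i])
  }
  star(network$focal, 0L)
}

#' Brute-force posterior over all parent presence/absence outcomes
#'
#' Independent test oracle for [resolve]: enumerates the 2^n joint
#' presence/absence outcomes of the parents, weights each by
#' `prod(q_j or 1-q_j)`, classifies it as increased / decreased / no change
#' under the OR or AND rule applied to the realised presences, and averages
#' the corresponding modified prior. Exponential in the parent count, hence
#' capped at 12 parents.
#'
#' @param prior scalar prior probability in \[0, 1\].
#' @param parents list of `(q, sign)` pairs (scalar probability + sign).
#' @param cfg a [resolution_config].
#' @return the scalar posterior probability.
#' @export
enumerate_posterior <- function(prior, parents = list(),
                                cfg = resolution_config()) {
  n <- length(parents)
  if (n > 12) stop("enumeration capped at 12 parents", call. = FALSE)
  stopifnot(prior >= 0, prior <= 1)
  q <- vapply(parents, function(p) p$q, numeric(1))
  sg <- vapply(parents, function(p) p$sign, character(1))
  p_up <- prior + cfg$alpha * (1 - prior)
  p_dn <- prior * (1 - cfg$alpha)
  post <- 0
  for (mask in 0:(2^n - 1)) {
    present <- if (n) as.logical(bitwAnd(mask, 2^(seq_len(n) - 1))) else logical(0)
    w <- prod(ifelse(present, q, 1 - q))
    fires <- function(sign) {
      members <- sg == sign
      if (!any(members)) return(FALSE)  # empty direction never fires
      if (cfg$method == "OR") any(present[members]) else all(present[members])
    }
    up <- fires("+"); dn <- fires("-")
    post <- post + w * if (up && !dn) p_up else if (dn && !up) p_dn else prior
  }
  post
}
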