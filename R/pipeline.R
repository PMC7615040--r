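# End-to-end orchestration: simulate -> clean -> fit -> resolve ->
# threshold -> report, driven by a declarative config and one master seed.
# Each stage is an exported function taking and returning the accumulating
# artifact list, so the numbered analysis scripts (and user code on real
# data) can run any stage independently; run_all() chains them and writes
# every intermediate to disk.

#' Bundled demonstration configuration
#'
#' A five-species virtual ecosystem on a 20 x 20 grid of 2-arcmin cells: a
#' focal insect, one food tree (positive interactor), one competitor that
#' suppresses the food tree through an indirect sub-network, and two
#' predators condensed to per-cell top-2 groups (negative interactors).
#' Two future scenarios apply moderate (+1.8 deg C, -10 percent rainfall)
#' and severe (+3.7 deg C, -20 percent rainfall) climate shifts; niche
#' optima sit slightly below the present temperature mean so warming pushes
#' habitat away, emulating a contracting savanna herbivore.
#'
#' @return a pipeline config list (YAML-serializable).
#' @export
demo_config <- function() {
  opt <- function(bio1, bio12) {
    list(bio1 = bio1, bio5 = bio1 + 9, bio6 = bio1 - 11,
         bio12 = bio12, bio13 = bio12 * 0.25, bio14 = bio12 * 0.025)
  }
  br <- function(t, p) {
    list(bio1 = t, bio5 = t * 1.3, bio6 = t * 1.3,
         bio12 = p, bio13 = p * 0.3, bio14 = p * 0.05)
  }
  list(
    grid = list(n_rows = 20, n_cols = 20, origin_lon = 20, origin_lat = -25,
                cell_size = 0.25, autocorr_range = 3),
    scenarios = list(
      rcp45 = list(delta_temp = 1.8, precip_factor = 0.9),
      rcp85 = list(delta_temp = 3.7, precip_factor = 0.8)),
    species = list(
      list(id = "focal_moth", role = "focal", sign_to_focal = "none",
           max_prob = 0.95, n_target = 150,
           optimum = opt(21, 480), breadth = br(2.5, 220),
           contamination = list(zeros = 3, equal_lonlat = 3,
                                institution = 3, sea = 3)),
      list(id = "food_tree", role = "food_tree", sign_to_focal = "+",
           max_prob = 0.95, n_target = 180,
           optimum = opt(21.5, 470), breadth = br(3, 260),
           contamination = list(zeros = 2, equal_lonlat = 2,
                                institution = 2, sea = 2)),
      list(id = "elephant", role = "competitor", sign_to_focal = "none",
           max_prob = 0.9, n_target = 160,
           optimum = opt(22.5, 430), breadth = br(4, 320),
           contamination = list()),
      list(id = "predator_a", role = "predator", sign_to_focal = "-",
           max_prob = 0.9, n_target = 160,
           optimum = opt(23, 450), breadth = br(3.5, 300),
           contamination = list()),
      list(id = "predator_b", role = "predator", sign_to_focal = "-",
           max_prob = 0.9, n_target = 160,
           optimum = opt(20, 520), breadth = br(3.5, 300),
           contamination = list())),
    network = list(
      focal = "focal_moth",
      method = "OR", alpha = 0.5, top_k = 2,
      edges = data.frame(
        parent = c("elephant", "food_tree", "pred_group_1", "pred_group_2"),
        child = c("food_tree", "focal_moth", "focal_moth", "focal_moth"),
        sign = c("-", "+", "-", "-"),
        subnetwork_order = c(1L, 0L, 0L, 0L))),
    sdm = list(algorithms = c("envelope", "logistic", "forest"),
               k = 4, n_trees = 500,
               background_multiplier = 10, background_max = 10000,
               min_records = 20),
    landscape = list(threshold_rule = "TSS", adjacency = "queen",
                     n_regions = 3))
}

#' Validate a pipeline configuration
#'
#' Collects every violation of the config invariants rather than stopping
#' at the first.
#'
#' @param config a pipeline config list.
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, sprintf(...))
  ids <- vapply(config$species, `[[`, "", "id")
  roles <- vapply(config$species, `[[`, "", "role")
  if (sum(roles == "focal") != 1) {
    say("config must declare exactly one focal species (found %d)",
        sum(roles == "focal"))
  }
  if (anyDuplicated(ids)) say("duplicate species ids")
  if (is.null(config$sdm$k) || config$sdm$k < 2) {
    say("cross-validation k must be >= 2")
  }
  n_pred <- sum(roles == "predator")
  if (!is.null(config$network$top_k) && config$network$top_k > n_pred &&
      n_pred > 0) {
    say("top_k (%d) exceeds the number of predator species (%d)",
        config$network$top_k, n_pred)
  }
  ed <- config$network$edges
  if (!is.null(ed) && nrow(ed)) {
    group_nodes <- grep("^pred_group_", unique(c(ed$parent, ed$child)),
                        value = TRUE)
    named <- setdiff(unique(c(ed$parent, ed$child)), group_nodes)
    unknown <- setdiff(named, ids)
    if (length(unknown)) {
      say("network references unknown species: %s",
          paste(unknown, collapse = ", "))
    }
    if (!all(ed$sign %in% c("+", "-"))) say("edge signs must be '+' or '-'")
    if (length(group_nodes) &&
        max(as.integer(sub("^pred_group_", "", group_nodes))) >
          (config$network$top_k %||% 0)) {
      say("predator group index exceeds top_k")
    }
  }
  if (!is.null(config$network$alpha) &&
      (config$network$alpha < 0 || config$network$alpha > 1)) {
    say("alpha must be in [0, 1]")
  }
  if (!is.null(config$network$method) &&
      !toupper(config$network$method) %in% c("OR", "AND")) {
    say("resolution method must be OR or AND")
  }
  if (!length(config$scenarios)) say("at least one future scenario required")
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

species_from_config <- function(config) {
  lapply(config$species, function(s) {
    virtual_species(s$id, unlist(s$optimum), unlist(s$breadth),
                    max_prob = s$max_prob, role = s$role,
                    sign_to_focal = s$sign_to_focal %||% "none")
  })
}

#' Stage 1: simulate the virtual ecosystem
#'
#' Generates the present climate grid, the future scenario grids, the
#' cleaning fixtures, the pseudo-country regions, and the contaminated
#' occurrence samples for every configured species.
#'
#' @param config a pipeline config list (see [demo_config]).
#' @param seed master seed; stage- and species-level seeds are derived from
#'   it deterministically.
#' @return an artifact list consumed by the later stages.
#' @export
stage_simulate <- function(config, seed) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  g <- config$grid
  present <- make_climate(derive_seed(seed, "climate"),
                          n_rows = g$n_rows, n_cols = g$n_cols,
                          origin_lon = g$origin_lon, origin_lat = g$origin_lat,
                          cell_size = g$cell_size,
                          autocorr_range = g$autocorr_range)
  grids <- list(present = present)
  for (sc in names(config$scenarios)) {
    s <- config$scenarios[[sc]]
    grids[[sc]] <- make_future(present, s$delta_temp, s$precip_factor,
                               scenario_tag = sc,
                               noise_sd = s$noise_sd %||% 0,
                               seed = derive_seed(seed, "future", sc))
  }
  fixtures <- make_fixtures(present, derive_seed(seed, "fixtures"))
  regions <- make_regions(present, config$landscape$n_regions %||% 3,
                          derive_seed(seed, "regions"))
  species <- species_from_config(config)
  occ <- do.call(rbind, lapply(seq_along(species), function(i) {
    s <- config$species[[i]]
    sample_occurrences(species[[i]], present, s$n_target,
                       derive_seed(seed, "occ", s$id),
                       contamination = s$contamination %||% list(),
                       fixtures = fixtures)
  }))
  list(config = config, seed = seed, grids = grids, species = species,
       fixtures = fixtures, regions = regions, occurrences_raw = occ)
}

#' Stage 2: filter, clean and rarefy the occurrence records
#'
#' Basis-of-record whitelist, coordinate-error cleaning against the
#' gazetteer and land mask, rarefaction to one record per grid cell, and
#' the minimum-record rule (evaluated on cleaned, rarefied counts).
#'
#' @param art artifact list from [stage_simulate].
#' @return `art` with `records`, `cleaning_report` and `species_status`
#'   added.
#' @export
stage_occurrences <- function(art) {
  keep <- filter_basis(art$occurrences_raw)
  cl <- clean_records(keep, art$fixtures$gazetteer, art$fixtures$land_mask)
  rar <- rarefy(cl$records, art$grids$present)
  art$records <- rar
  art$cleaning_report <- cl$report
  art$species_status <- require_min_records(
    rar, art$config$sdm$min_records %||% 20)
  art
}

make_fitters <- function(config, seed, species_id) {
  n_trees <- config$sdm$n_trees %||% 500
  list(
    envelope = function(p, b, g) fit_envelope(p, g),
    logistic = function(p, b, g) {
      fit_logistic(p, b, g, seed = derive_seed(seed, "glm", species_id))
    },
    forest = function(p, b, g) {
      fit_forest(p, b, g, seed = derive_seed(seed, "rf", species_id),
                 n_trees = n_trees)
    })[config$sdm$algorithms]
}

#' Stage 3: fit, cross-validate, project and ensemble the SDMs
#'
#' For every retained species: a uniform background sample, the three
#' algorithm fits, k-fold cross-validated AUC (shared fold assignment
#' across algorithms), projection onto every scenario grid, and the
#' AUC-weighted ensemble per scenario.
#'
#' @param art artifact list from [stage_occurrences].
#' @return `art` with an `sdm` element keyed by species id.
#' @export
stage_sdms <- function(art) {
  config <- art$config; seed <- art$seed
  grid <- art$grids$present
  k <- config$sdm$k %||% 4
  art$sdm <- list()
  retained <- art$species_status$species[art$species_status$retained]
  for (id in retained) {
    pres <- art$records[art$records$species == id, , drop = FALSE]
    n_cells <- grid$n_rows * grid$n_cols
    n_bg <- min(config$sdm$background_max %||% 10000,
                (config$sdm$background_multiplier %||% 10) * nrow(pres),
                n_cells - nrow(pres))
    bg <- sample_background(grid, n_bg, derive_seed(seed, "bg", id),
                            exclude = pres)
    fitters <- make_fitters(config, seed, id)
    cv_seed <- derive_seed(seed, "cv", id)
    cv <- lapply(fitters, function(f) {
      kfold_auc(f, pres, bg, grid, k = k, seed = cv_seed)
    })
    models <- lapply(fitters, function(f) f(pres, bg, grid))
    proj <- lapply(art$grids, function(g) {
      lapply(models, project, grid = g, species_id = id)
    })
    weights <- vapply(cv, `[[`, numeric(1), "mean_auc")
    ens <- lapply(proj, function(pr) ensemble(pr, weights, species_id = id))
    art$sdm[[id]] <- list(presences = pres, background = bg, models = models,
                          cv = cv, projections = proj, weights = weights,
                          ensembles = ens)
  }
  art
}

# Priors map for one algorithm and scenario: per-algorithm rasters for the
# focal and every sub-network focal (their SDMs are re-resolved), ensembled
# rasters for pure parents, condensed group rasters for pred_group_* nodes.
network_priors <- function(art, network, alg, scenario, condensed) {
  nodes <- unique(c(network$edges$parent, network$edges$child, network$focal))
  per_alg <- c(network$focal, network$sub_focals)
  priors <- list()
  for (nd in nodes) {
    priors[[nd]] <- if (grepl("^pred_group_", nd)) {
      condensed[[as.integer(sub("^pred_group_", "", nd))]]
    } else if (nd %in% per_alg) {
      art$sdm[[nd]]$projections[[scenario]][[alg]]
    } else {
      art$sdm[[nd]]$ensembles[[scenario]]
    }
    if (is.null(priors[[nd]])) stop("no raster available for node ", nd)
  }
  priors
}

#' Stage 4: resolve the interaction network over the SDM priors
#'
#' Condenses predator ensembles to per-cell top-k group rasters, resolves
#' the sub-networks and the focal star per algorithm and scenario,
#' re-evaluates each algorithm by k-fold AUC with the parent rasters held
#' fixed (only the focal SDM is refitted per fold), and combines the
#' per-algorithm posteriors into an AUC-weighted posterior ensemble.
#'
#' @param art artifact list from [stage_sdms].
#' @return `art` with a `network` element: per-scenario posteriors and
#'   posterior ensembles, the network CV table and weights.
#' @export
stage_network <- function(art) {
  config <- art$config
  net_cfg <- config$network
  cfg <- resolution_config(net_cfg$method %||% "OR", net_cfg$alpha %||% 0.5)
  network <- interaction_network(net_cfg$edges %||% data.frame(),
                                 net_cfg$focal)
  focal <- net_cfg$focal
  if (is.null(art$sdm[[focal]])) stop("focal species was not modelled")
  algs <- config$sdm$algorithms
  uses_groups <- any(grepl("^pred_group_", network$edges$parent))
  predators <- vapply(
    Filter(function(s) s$role == "predator", config$species), `[[`, "", "id")
  predators <- intersect(predators, names(art$sdm))

  condensed <- list()
  posteriors <- list()
  for (sc in names(art$grids)) {
    condensed[[sc]] <- if (uses_groups) {
      condense_top_k(lapply(predators,
                            function(id) art$sdm[[id]]$ensembles[[sc]]),
                     k = net_cfg$top_k %||% 3)
    } else list()
    posteriors[[sc]] <- lapply(algs, function(a) {
      resolve_chain(network,
                    network_priors(art, network, a, sc, condensed[[sc]]),
                    cfg)
    })
    names(posteriors[[sc]]) <- algs
  }

  # network CV: parent rasters fixed at their full-data present values,
  # focal SDM refit per fold, posterior scored on the held-out points;
  # fold assignment matches the no-network CV (same derived seed)
  fo <- art$sdm[[focal]]
  fitters <- make_fitters(config, art$seed, focal)
  cv_seed <- derive_seed(art$seed, "cv", focal)
  net_cv <- lapply(algs, function(a) {
    pri <- network_priors(art, network, a, "present", condensed$present)
    kfold_auc(fitters[[a]], fo$presences, fo$background, art$grids$present,
              k = config$sdm$k %||% 4, seed = cv_seed,
              transform = function(r) {
                pri[[focal]] <- r
                resolve_chain(network, pri, cfg)
              })
  })
  names(net_cv) <- algs
  net_weights <- vapply(net_cv, `[[`, numeric(1), "mean_auc")
  post_ens <- lapply(posteriors, function(pr) {
    ensemble(pr, net_weights, species_id = focal)
  })
  art$network <- list(network = network, cfg = cfg, condensed = condensed,
                      posteriors = posteriors, cv = net_cv,
                      weights = net_weights, ensembles = post_ens)
  art
}

#' Stage 5: threshold and summarise the landscape
#'
#' For both branches (plain ensemble and network posterior ensemble):
#' estimates the TSS and prevalence thresholds on the present-period model
#' (re-used unchanged for future projections), binarizes every scenario,
#' and builds the per-scenario, per-region landscape report.
#'
#' @param art artifact list from [stage_network] (the `no_network` branch
#'   alone also works on the output of [stage_sdms]).
#' @return `art` with a `landscape` element keyed by branch.
#' @export
stage_landscape <- function(art) {
  config <- art$config
  focal <- config$network$focal
  fo <- art$sdm[[focal]]
  rule <- config$landscape$threshold_rule %||% "TSS"
  adjacency <- config$landscape$adjacency %||% "queen"
  branches <- list(no_network = fo$ensembles)
  if (!is.null(art$network)) branches$network <- art$network$ensembles
  art$landscape <- lapply(branches, function(ens) {
    thr <- list(
      TSS = tss_threshold(ens$present, fo$presences, fo$background),
      Prevalence = prevalence_threshold(ens$present, fo$presences,
                                        fo$background))
    t_use <- thr[[rule]]$threshold
    maps <- lapply(ens, binarize, t = t_use, rule = rule)
    list(thresholds = thr, maps = maps,
         report = landscape_report(maps, art$regions,
                                   adjacency = adjacency))
  })
  art
}

write_artifacts <- function(art, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_occurrences(art$occurrences_raw, p("occurrences_raw.csv"))
  write_occurrences(art$records, p("occurrences_clean.csv"))
  write_cleaning_report(art$cleaning_report, p("cleaning_report.txt"))
  write.csv(art$species_status, p("species_status.csv"), row.names = FALSE)
  dir.create(p("rasters"), showWarnings = FALSE)
  for (id in names(art$sdm)) {
    write_cv_table(art$sdm[[id]]$cv, p(sprintf("cv_%s.csv", id)))
    for (sc in names(art$sdm[[id]]$ensembles)) {
      write_ascii_grid(art$sdm[[id]]$ensembles[[sc]],
                       p("rasters", sprintf("ensemble_%s_%s.asc", id, sc)))
    }
  }
  if (!is.null(art$network)) {
    write_cv_table(art$network$cv, p("cv_network.csv"))
    write_network(art$network$network, p("network_edges.csv"))
    for (sc in names(art$network$ensembles)) {
      write_ascii_grid(art$network$ensembles[[sc]],
                       p("rasters", sprintf("posterior_ensemble_%s.asc", sc)))
    }
  }
  for (br in names(art$landscape)) {
    l <- art$landscape[[br]]
    write.csv(l$report, p(sprintf("landscape_report_%s.csv", br)),
              row.names = FALSE)
    for (sc in names(l$maps)) {
      write_ascii_grid(l$maps[[sc]],
                       p("rasters", sprintf("habitat_%s_%s.asc", br, sc)))
    }
  }
  write_ascii_grid(art$regions, p("rasters", "regions.asc"),
                   g = art$grids$present)
  write_config(art$config, p("config.yaml"))
  writeLines(c(sprintf("seed: %d", art$seed),
               sprintf("package: bnsdm %s",
                       as.character(utils::packageVersion("bnsdm"))),
               sprintf("r_version: %s", R.version.string)),
             p("manifest.txt"))
  invisible(out_dir)
}

#' Run the full pipeline
#'
#' Chains all five stages under one master seed; identical config + seed
#' give identical outputs. When `out_dir` is given, every intermediate
#' (occurrence tables, cleaning report, CV tables, ensemble and posterior
#' rasters, binary maps, landscape reports, config and run manifest) is
#' written there as plain text.
#'
#' @param config a pipeline config list; [demo_config()] by default.
#' @param seed master seed.
#' @param out_dir optional artifact directory.
#' @return the full artifact list (invisibly when `out_dir` is set).
#' @export
run_all <- function(config = demo_config(), seed = 1, out_dir = NULL) {
  art <- stage_simulate(config, seed)
  art <- stage_occurrences(art)
  art <- stage_sdms(art)
  art <- stage_network(art)
  art <- stage_landscape(art)
  if (!is.null(out_dir)) {
    write_artifacts(art, out_dir)
    return(invisible(art))
  }
  art
}
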