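# The three suitability algorithms (climate envelope, quadratic logistic
# regression, random forest), rank-based AUC, k-fold cross-validation, grid
# projection and AUC-weighted ensembling.

# Accept either occurrence-style (decimalLongitude/decimalLatitude) or plain
# lon/lat point tables.
get_lonlat <- function(points) {
  if (all(c("lon", "lat") %in% names(points))) {
    data.frame(lon = points$lon, lat = points$lat)
  } else if (all(c("decimalLongitude", "decimalLatitude") %in% names(points))) {
    data.frame(lon = points$decimalLongitude, lat = points$decimalLatitude)
  } else {
    stop("points need lon/lat or decimalLongitude/decimalLatitude columns",
         call. = FALSE)
  }
}

training_matrix <- function(points, grid) {
  ll <- get_lonlat(points)
  x <- extract_climate(grid, ll$lon, ll$lat)
  if (anyNA(x)) stop("points fall on masked or off-grid cells", call. = FALSE)
  x
}

#' Draw background (pseudo-absence) cells
#'
#' Uniform draw without replacement over non-masked grid cells, excluding
#' cells occupied by presences by default. Returned points are cell
#' centres.
#'
#' @param grid a [climate_grid].
#' @param n number of background points (>= 1).
#' @param seed integer seed.
#' @param exclude optional point table whose cells are excluded (the
#'   presences).
#' @param mask optional [binary_map]; FALSE cells are unavailable.
#' @return data.frame with columns `lon`, `lat`.
#' @export
sample_background <- function(grid, n, seed, exclude = NULL, mask = NULL) {
  stopifnot(n >= 1)
  avail <- rep(TRUE, grid$n_rows * grid$n_cols)
  if (!is.null(mask)) {
    stop_if_misaligned(grid, mask)
    avail <- avail & as.vector(mask$presence)
  }
  if (!is.null(exclude) && nrow(exclude) > 0) {
    ll <- get_lonlat(exclude)
    idx <- cell_index(grid, ll$lon, ll$lat)
    ok <- !is.na(idx$row)
    avail[(idx$col[ok] - 1L) * grid$n_rows + idx$row[ok]] <- FALSE
  }
  cells <- which(avail)
  if (n > length(cells)) {
    stop(sprintf("requested %d background cells but only %d available",
                 n, length(cells)), call. = FALSE)
  }
  picked <- with_seed(seed, sample(cells, n))
  rc <- arrayInd(picked, c(grid$n_rows, grid$n_cols))
  data.frame(lon = col_center_lon(grid, rc[, 2]),
             lat = row_center_lat(grid, rc[, 1]))
}

#' Fit a climate-envelope (BIOCLIM-style) model
#'
#' Stores the sorted training values of each bioclim variable at the
#' presence cells. Projection scores a cell by the mid-rank percentile
#' position of its value inside each envelope:
#' `F_v = (count_less + 0.5 * count_equal) / n`, per-variable score
#' `2 * min(F_v, 1 - F_v)`, cell score the minimum over variables. Values
#' outside the training range score 0.
#'
#' @param presences presence point table.
#' @param grid a [climate_grid].
#' @return an `sdm_model` with `algorithm = "envelope"`.
#' @export
fit_envelope <- function(presences, grid) {
  x <- training_matrix(presences, grid)
  if (nrow(x) < 2) stop("envelope fitting needs >= 2 presences", call. = FALSE)
  structure(list(algorithm = "envelope",
                 train = apply(x, 2, sort, simplify = FALSE),
                 n_presence = nrow(x)),
            class = "sdm_model")
}

envelope_score <- function(model, x) {
  sc <- matrix(NA_real_, nrow(x), length(model$train))
  for (j in seq_along(model$train)) {
    v <- model$train[[j]]
    n <- length(v)
    less <- findInterval(x[, j], v, left.open = TRUE)
    lesseq <- findInterval(x[, j], v)
    f <- (less + 0.5 * (lesseq - less)) / n
    sc[, j] <- 2 * pmin(f, 1 - f)
  }
  apply(sc, 1, min)
}

#' Fit a logistic-regression suitability model
#'
#' Presence (1) vs background (0) logistic regression on the six bioclim
#' variables, standardised to training mean/sd, with linear and quadratic
#' terms so unimodal climate responses are expressible. On perfect
#' separation or non-convergence the fit is redone with a small ridge
#' penalty and a warning is issued.
#'
#' @param presences,background point tables (both non-empty).
#' @param grid a [climate_grid].
#' @param seed integer seed (used only by the ridge fallback's internals;
#'   the plain fit is deterministic).
#' @return an `sdm_model` with `algorithm = "logistic"`.
#' @export
fit_logistic <- function(presences, background, grid, seed = NULL) {
  xp <- training_matrix(presences, grid)
  xb <- training_matrix(background, grid)
  if (!nrow(xp) || !nrow(xb)) stop("both classes must be non-empty")
  x <- rbind(xp, xb)
  y <- c(rep(1L, nrow(xp)), rep(0L, nrow(xb)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  zz <- cbind(z, z^2)
  colnames(zz) <- c(colnames(x), paste0(colnames(x), "_sq"))
  dat <- data.frame(y = y, zz, check.names = FALSE)
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  cf <- stats::coef(fit)
  # exploding standardized coefficients indicate (quasi-)separation
  if (!fit$converged || max(abs(cf), na.rm = TRUE) > 15) {
    warning("logistic fit unstable (separation?); refitting with ridge penalty")
    rf <- with_seed(seed, glmnet::glmnet(zz, y, family = "binomial",
                                         alpha = 0, lambda = 1e-3))
    beta <- c(as.numeric(rf$a0), as.numeric(rf$beta))
  } else {
    beta <- cf
    beta[is.na(beta)] <- 0
  }
  structure(list(algorithm = "logistic", beta = unname(beta),
                 center = ctr, scale = scl,
                 n_presence = nrow(xp), n_background = nrow(xb)),
            class = "sdm_model")
}

logistic_score <- function(model, x) {
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  eta <- model$beta[1] + cbind(z, z^2) %*% model$beta[-1]
  as.numeric(plogis(eta))
}

#' Fit a random-forest suitability model
#'
#' Classification forest of presence vs background; projected suitability is
#' the fraction of trees voting presence. 500 trees and
#' `floor(sqrt(6)) = 2` split candidates per node by default; seeded and
#' reproducible.
#'
#' @inheritParams fit_logistic
#' @param n_trees number of trees.
#' @return an `sdm_model` with `algorithm = "forest"`.
#' @export
fit_forest <- function(presences, background, grid, seed, n_trees = 500) {
  xp <- training_matrix(presences, grid)
  xb <- training_matrix(background, grid)
  if (!nrow(xp) || !nrow(xb)) stop("both classes must be non-empty")
  x <- rbind(xp, xb)
  y <- factor(c(rep("presence", nrow(xp)), rep("background", nrow(xb))),
              levels = c("background", "presence"))
  rf <- with_seed(seed,
                  randomForest::randomForest(x, y, ntree = n_trees,
                                             mtry = floor(sqrt(ncol(x)))))
  structure(list(algorithm = "forest", forest = rf,
                 n_presence = nrow(xp), n_background = nrow(xb)),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s, %d presences\n", x$algorithm, x$n_presence))
  invisible(x)
}

score_matrix <- function(model, x) {
  switch(model$algorithm,
         envelope = envelope_score(model, x),
         logistic = logistic_score(model, x),
         forest = stats::predict(model$forest, x,
                                 type = "prob")[, "presence"],
         stop("unknown algorithm ", model$algorithm))
}

#' Project a fitted model onto a climate grid
#'
#' Applies the model cell-wise; cells with missing climate stay masked.
#'
#' @param model an `sdm_model`.
#' @param grid a [climate_grid] carrying the model's variables.
#' @param species_id label recorded in the output provenance.
#' @return a [suitability_raster].
#' @export
project <- function(model, grid, species_id = NA_character_) {
  vars <- bioclim_vars()
  if (!all(vars %in% names(grid$layers))) {
    stop("grid lacks the model's variables", call. = FALSE)
  }
  x <- sapply(vars, function(v) as.vector(grid$layers[[v]]))
  ok <- complete.cases(x)
  vals <- rep(NA_real_, nrow(x))
  if (any(ok)) vals[ok] <- score_matrix(model, x[ok, , drop = FALSE])
  suitability_raster(grid, matrix(vals, grid$n_rows, grid$n_cols),
                     species_id = species_id, source = model$algorithm)
}

#' Score a suitability raster at point locations
#'
#' @param raster a [suitability_raster].
#' @param points point table.
#' @return numeric vector of per-point suitabilities (`NA` off-grid).
#' @export
extract_suitability <- function(raster, points) {
  ll <- get_lonlat(points)
  idx <- cell_index(raster, ll$lon, ll$lat)
  v <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  v[ok] <- raster$values[cbind(idx$row[ok], idx$col[ok])]
  v
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Fraction of (presence, background) score pairs where the presence scores
#' higher, counting ties as one half; equivalently the normalised
#' Mann-Whitney U computed from mid-ranks.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' k-fold cross-validated AUC
#'
#' Presences and background are partitioned independently into `k` seeded
#' folds (stratified by class); for each fold the model is refitted on the
#' remaining k-1 folds and scored by AUC on the held-out presences against
#' the held-out background.
#'
#' @param fitter function `(presences, background, grid) -> sdm_model`.
#' @param presences,background point tables, each with >= k points.
#' @param grid a [climate_grid].
#' @param k number of folds (default 4).
#' @param seed integer seed for fold assignment.
#' @param transform optional function applied to each fold's projected
#'   raster before scoring (used to evaluate network-resolved models with
#'   the parent rasters held fixed).
#' @return a `cv_summary`: list with `fold_auc`, `mean_auc`, `sd_auc`, `k`.
#' @export
kfold_auc <- function(fitter, presences, background, grid, k = 4, seed = 1,
                      transform = NULL) {
  np <- nrow(presences); nb <- nrow(background)
  if (k > np || k > nb) stop("k exceeds a class size", call. = FALSE)
  folds <- with_seed(seed, list(
    p = sample(rep_len(seq_len(k), np)),
    b = sample(rep_len(seq_len(k), nb))))
  fold_auc <- vapply(seq_len(k), function(i) {
    m <- fitter(presences[folds$p != i, , drop = FALSE],
                background[folds$b != i, , drop = FALSE], grid)
    r <- project(m, grid)
    if (!is.null(transform)) r <- transform(r)
    auc(extract_suitability(r, presences[folds$p == i, , drop = FALSE]),
        extract_suitability(r, background[folds$b == i, , drop = FALSE]))
  }, numeric(1))
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 sd_auc = sd(fold_auc), k = k),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %d-fold AUC %.3f +/- %.3f\n",
              x$k, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' AUC-weighted ensemble of suitability rasters
#'
#' Cell-wise weighted mean `sum(w_a * s_a) / sum(w_a)`; a cell masked in any
#' input is masked in the output.
#'
#' @param rasters list of aligned [suitability_raster]s.
#' @param weights non-negative weights, not all zero (typically each
#'   algorithm's mean cross-validated AUC).
#' @param species_id provenance label.
#' @return a [suitability_raster] with `source = "ensemble"`.
#' @export
ensemble <- function(rasters, weights, species_id = NA_character_) {
  stopifnot(length(rasters) >= 1, length(weights) == length(rasters))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  for (r in rasters[-1]) stop_if_misaligned(rasters[[1]], r)
  acc <- 0
  for (i in seq_along(rasters)) acc <- acc + weights[i] * rasters[[i]]$values
  suitability_raster(rasters[[1]], acc / sum(weights),
                     species_id = species_id, source = "ensemble",
                     scenario_tag = rasters[[1]]$scenario_tag)
}
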