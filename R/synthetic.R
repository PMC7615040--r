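# Virtual ecosystem generators: autocorrelated climate surfaces, Gaussian
# niche virtual species, Bernoulli occurrence sampling with injected
# erroneous records, and cleaning fixtures (land mask, gazetteer). These
# stand in for real climatology rasters and aggregator occurrence downloads
# so the whole pipeline is exercisable (and testable against known truth) at
# desk scale.

# Smooth a matrix with a separable Gaussian kernel of standard deviation
# `range` cells, renormalising at the edges so the mean level is preserved.
smooth_field <- function(m, range) {
  if (range <= 0) return(m)
  h <- max(1L, ceiling(3 * range))
  w <- stats::dnorm(seq(-h, h), sd = range)
  sm_1d <- function(x) {
    n <- length(x)
    num <- numeric(n); den <- numeric(n)
    for (k in seq_along(w)) {
      off <- k - h - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      num[ok] <- num[ok] + w[k] * x[src[ok]]
      den[ok] <- den[ok] + w[k]
    }
    num / den
  }
  m <- apply(m, 2, sm_1d)
  t(apply(m, 1, sm_1d))
}

#' Generate a synthetic present-day bioclimatic grid
#'
#' Builds six spatially autocorrelated bioclimatic surfaces (bio1, bio5,
#' bio6, bio12, bio13, bio14) on a regular lon/lat grid by smoothing seeded
#' white noise with a Gaussian kernel and rescaling to plausible southern
#' savanna ranges (temperatures in deg C around 22, annual rainfall around
#' 450 mm). The temperature ordering bio5 >= bio1 >= bio6 is enforced
#' constructively (mean plus/minus strictly positive offsets), and the
#' wettest-month share is kept above the driest-month share so precipitation
#' layers are internally consistent.
#'
#' @param seed integer seed; the output is a pure function of
#'   (seed, arguments).
#' @param n_rows,n_cols grid dimensions (each >= 2).
#' @param origin_lon,origin_lat lower-left corner in degrees.
#' @param cell_size cell edge in degrees; default 2 arcmin (1/30 deg), the
#'   working resolution of the analysis.
#' @param autocorr_range Gaussian smoothing range in cells (>= 0; 0 gives
#'   white noise).
#' @return a [climate_grid] with `scenario_tag = "present"`.
#' @export
make_climate <- function(seed, n_rows = 40, n_cols = 40,
                         origin_lon = 20, origin_lat = -25,
                         cell_size = 1 / 30, autocorr_range = 3) {
  if (n_rows < 2 || n_cols < 2) {
    stop("grid dimensions must be at least 2x2", call. = FALSE)
  }
  if (autocorr_range < 0) stop("autocorr_range must be >= 0", call. = FALSE)
  with_seed(seed, {
    z <- replicate(6, smooth_field(matrix(rnorm(n_rows * n_cols),
                                          n_rows, n_cols),
                                   autocorr_range),
                   simplify = FALSE)
    # restore unit variance lost to smoothing so niche breadths stay
    # comparable across autocorrelation ranges
    z <- lapply(z, function(m) {
      s <- sd(as.vector(m))
      if (s > 0) (m - mean(m)) / s else m
    })
    bio1  <- 22 + 4 * z[[1]]
    bio5  <- bio1 + 8 + 2 * abs(z[[2]])   # strictly positive offset
    bio6  <- bio1 - (10 + 2 * abs(z[[3]]))
    bio12 <- pmax(450 + 250 * z[[4]], 0)
    wet_share <- 0.20 + 0.10 * plogis(z[[5]])  # in (0.20, 0.30)
    dry_share <- 0.05 * plogis(z[[6]])         # in (0, 0.05)
    climate_grid(origin_lon, origin_lat, cell_size,
                 layers = list(bio1 = bio1, bio5 = bio5, bio6 = bio6,
                               bio12 = bio12,
                               bio13 = bio12 * wet_share,
                               bio14 = bio12 * dry_share),
                 scenario_tag = "present")
  })
}

#' Derive a future-scenario grid by additive warming and rainfall scaling
#'
#' Temperature layers are shifted by `delta_temp` degrees (optionally with
#' seeded cell-wise noise), precipitation layers are multiplied by
#' `precip_factor`. Georeferencing is unchanged.
#'
#' @param grid a present-day [climate_grid].
#' @param delta_temp uniform warming in deg C.
#' @param precip_factor multiplicative rainfall change (> 0).
#' @param scenario_tag label for the output scenario.
#' @param noise_sd standard deviation of optional seeded temperature noise
#'   (deg C); 0 disables it.
#' @param seed seed for the noise (ignored when `noise_sd = 0`).
#' @return a [climate_grid] for the future scenario.
#' @export
make_future <- function(grid, delta_temp, precip_factor,
                        scenario_tag = "future", noise_sd = 0, seed = NULL) {
  stopifnot(inherits(grid, "climate_grid"))
  if (precip_factor <= 0) stop("precip_factor must be > 0", call. = FALSE)
  eps <- if (noise_sd > 0) {
    with_seed(seed, matrix(rnorm(grid$n_rows * grid$n_cols, sd = noise_sd),
                           grid$n_rows, grid$n_cols))
  } else 0
  ly <- grid$layers
  for (v in c("bio1", "bio5", "bio6")) ly[[v]] <- ly[[v]] + delta_temp + eps
  for (v in c("bio12", "bio13", "bio14")) ly[[v]] <- ly[[v]] * precip_factor
  climate_grid(grid$origin_lon, grid$origin_lat, grid$cell_size,
               layers = ly, scenario_tag = scenario_tag)
}

#' Define a virtual species with an axis-aligned Gaussian climate niche
#'
#' True suitability at climate x is
#' `max_prob * exp(-0.5 * sum_v ((x_v - optimum_v) / breadth_v)^2)`,
#' a closed form that parameter-recovery tests can check against.
#'
#' @param species_id label.
#' @param niche_optimum named numeric vector over the six bioclim variables.
#' @param niche_breadth named positive numeric vector, same variables.
#' @param max_prob peak occurrence probability in (0, 1].
#' @param role one of `"focal"`, `"food_tree"`, `"predator"`,
#'   `"competitor"`.
#' @param sign_to_focal `"+"`, `"-"` or `"none"` (direct edge sign).
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(species_id, niche_optimum, niche_breadth,
                            max_prob = 1, role = "focal",
                            sign_to_focal = "none") {
  vars <- bioclim_vars()
  stopifnot(all(vars %in% names(niche_optimum)),
            all(vars %in% names(niche_breadth)),
            all(niche_breadth[vars] > 0),
            max_prob > 0, max_prob <= 1,
            role %in% c("focal", "food_tree", "predator", "competitor"),
            sign_to_focal %in% c("+", "-", "none"))
  structure(list(species_id = species_id,
                 niche_optimum = niche_optimum[vars],
                 niche_breadth = niche_breadth[vars],
                 max_prob = max_prob, role = role,
                 sign_to_focal = sign_to_focal),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' Evaluates the species' Gaussian niche kernel cell-wise over a climate
#' grid; this is the ground truth that sampled occurrences are drawn from.
#'
#' @param sp a [virtual_species].
#' @param grid a [climate_grid] carrying the six bioclim layers.
#' @return a [suitability_raster] with `source = "truth"`.
#' @export
true_suitability <- function(sp, grid) {
  stopifnot(inherits(sp, "virtual_species"), inherits(grid, "climate_grid"))
  vars <- bioclim_vars()
  if (!all(vars %in% names(grid$layers))) {
    stop("grid lacks the six bioclim layers", call. = FALSE)
  }
  d2 <- 0
  for (v in vars) {
    d2 <- d2 + ((grid$layers[[v]] - sp$niche_optimum[[v]]) /
                  sp$niche_breadth[[v]])^2
  }
  suitability_raster(grid, sp$max_prob * exp(-0.5 * d2),
                     species_id = sp$species_id, source = "truth")
}

#' Sample occurrence records from a virtual species
#'
#' Draws `n_target` presence cells with probability proportional to the
#' species' true suitability (with replacement, so rarefaction has
#' duplicates to remove), jitters each record uniformly within its source
#' cell, and appends the erroneous records requested by
#' `contamination`: plain-zero coordinates, equal lon/lat, points within
#' 1 degree of a gazetteer institution, and at-sea points from the land
#' mask. Clean records carry a basis-of-record drawn from the accepted
#' classes; contaminated ones are marked `"HUMAN_OBSERVATION"` so only the
#' coordinate tests can catch them.
#'
#' @param sp a [virtual_species].
#' @param grid a [climate_grid].
#' @param n_target number of clean records to draw (>= 1).
#' @param seed integer seed.
#' @param contamination named list with any of `zeros`, `equal_lonlat`,
#'   `institution`, `sea` (counts, default 0 each).
#' @param fixtures the land mask / gazetteer pair from [make_fixtures];
#'   required when `institution` or `sea` counts are positive.
#' @return an occurrence data.frame with columns `species`,
#'   `decimalLongitude`, `decimalLatitude`, `basisOfRecord`.
#' @export
sample_occurrences <- function(sp, grid, n_target, seed,
                               contamination = list(), fixtures = NULL) {
  stopifnot(n_target >= 1)
  truth <- true_suitability(sp, grid)
  p <- as.vector(truth$values)
  con <- utils::modifyList(list(zeros = 0, equal_lonlat = 0,
                                institution = 0, sea = 0), contamination)
  with_seed(seed, {
    if (sum(p) <= 0) {
      warning("no suitable cells; returning contamination-only records")
      cells <- integer(0)
    } else {
      cells <- sample.int(length(p), n_target, replace = TRUE, prob = p)
    }
    rc <- arrayInd(cells, c(grid$n_rows, grid$n_cols))
    lon <- grid$origin_lon + (rc[, 2] - runif(length(cells))) * grid$cell_size
    lat <- grid$origin_lat +
      (grid$n_rows - rc[, 1] + runif(length(cells))) * grid$cell_size
    basis <- sample(c("HUMAN_OBSERVATION", "MACHINE_OBSERVATION",
                      "LIVING_SPECIMEN"),
                    length(cells), replace = TRUE, prob = c(0.7, 0.2, 0.1))
    recs <- data.frame(species = rep(sp$species_id, length(cells)),
                       decimalLongitude = lon, decimalLatitude = lat,
                       basisOfRecord = basis, stringsAsFactors = FALSE)
    bad <- list()
    if (con$zeros > 0) {
      bad$zeros <- data.frame(species = sp$species_id,
                              decimalLongitude = rep(0, con$zeros),
                              decimalLatitude = rep(0, con$zeros),
                              basisOfRecord = "HUMAN_OBSERVATION")
    }
    if (con$equal_lonlat > 0) {
      # typically off-grid (as with real transposed-coordinate errors);
      # cleaning counts them under both equal-lon/lat and out-of-range
      v <- round(runif(con$equal_lonlat, 5, 15), 4)
      bad$eq <- data.frame(species = sp$species_id, decimalLongitude = v,
                           decimalLatitude = v,
                           basisOfRecord = "HUMAN_OBSERVATION")
    }
    if (con$institution > 0) {
      if (is.null(fixtures)) stop("institution contamination needs fixtures")
      inst <- fixtures$gazetteer[fixtures$gazetteer$type == "institution", ]
      i <- sample.int(nrow(inst), con$institution, replace = TRUE)
      ang <- runif(con$institution, 0, 2 * pi)
      rad <- runif(con$institution, 0, 0.9)
      bad$inst <- data.frame(species = sp$species_id,
                             decimalLongitude = inst$lon[i] + rad * cos(ang),
                             decimalLatitude = inst$lat[i] + rad * sin(ang),
                             basisOfRecord = "HUMAN_OBSERVATION")
    }
    if (con$sea > 0) {
      if (is.null(fixtures)) stop("sea contamination needs fixtures")
      sea_cells <- which(!fixtures$land_mask$presence)
      if (!length(sea_cells)) stop("land mask has no sea cells")
      i <- sea_cells[sample.int(length(sea_cells), con$sea, replace = TRUE)]
      rc <- arrayInd(i, c(grid$n_rows, grid$n_cols))
      bad$sea <- data.frame(
        species = sp$species_id,
        decimalLongitude = col_center_lon(grid, rc[, 2]),
        decimalLatitude = row_center_lat(grid, rc[, 1]),
        basisOfRecord = "HUMAN_OBSERVATION")
    }
    do.call(rbind, c(list(recs), unname(bad)))
  })
}

#' Generate cleaning fixtures: a land mask and a gazetteer
#'
#' The land mask is a smoothed-noise coastline aligned to the analysis grid
#' (roughly 85 percent land, guaranteed to contain at least one land and one
#' sea cell). The gazetteer lists labelled points of the kinds coordinate
#' cleaning tests against: country capitals, country centroids, and
#' biodiversity institutions.
#'
#' @param grid a [climate_grid] the mask is aligned to.
#' @param seed integer seed.
#' @return list with `land_mask` (a [binary_map], TRUE = land) and
#'   `gazetteer` (data.frame `name`, `type`, `lon`, `lat`).
#' @export
make_fixtures <- function(grid, seed) {
  stopifnot(inherits(grid, "climate_grid"))
  with_seed(seed, {
    f <- smooth_field(matrix(rnorm(grid$n_rows * grid$n_cols),
                             grid$n_rows, grid$n_cols), 3)
    land <- f > quantile(f, 0.15)
    land[1] <- FALSE  # guarantee at least one sea cell
    land[length(land)] <- TRUE
    mask <- binary_map(grid, land, rule = "manual")
    pick_cell <- function(n) {
      i <- sample.int(grid$n_rows * grid$n_cols, n)
      rc <- arrayInd(i, c(grid$n_rows, grid$n_cols))
      data.frame(lon = col_center_lon(grid, rc[, 2]),
                 lat = row_center_lat(grid, rc[, 1]))
    }
    caps <- pick_cell(2); cents <- pick_cell(2); insts <- pick_cell(2)
    gaz <- rbind(
      data.frame(name = paste0("capital_", 1:2), type = "capital", caps),
      data.frame(name = paste0("centroid_", 1:2), type = "centroid", cents),
      data.frame(name = paste0("institution_", 1:2), type = "institution",
                 insts))
    list(land_mask = mask, gazetteer = gaz)
  })
}

#' Partition the grid into contiguous pseudo-country regions
#'
#' Voronoi assignment of cells to seeded anchor cells, giving contiguous
#' region labels for per-region habitat reporting (the synthetic analogue
#' of a country raster).
#'
#' @param grid a [climate_grid].
#' @param n_regions number of regions (>= 1).
#' @param seed integer seed.
#' @return integer matrix of region labels (1..n_regions), grid-shaped.
#' @export
make_regions <- function(grid, n_regions = 3, seed = 1) {
  stopifnot(n_regions >= 1)
  with_seed(seed, {
    anchors <- arrayInd(sample.int(grid$n_rows * grid$n_cols, n_regions),
                        c(grid$n_rows, grid$n_cols))
    rows <- matrix(rep(seq_len(grid$n_rows), grid$n_cols),
                   grid$n_rows, grid$n_cols)
    cols <- matrix(rep(seq_len(grid$n_cols), each = grid$n_rows),
                   grid$n_rows, grid$n_cols)
    d <- array(0, c(grid$n_rows, grid$n_cols, n_regions))
    for (k in seq_len(n_regions)) {
      d[, , k] <- (rows - anchors[k, 1])^2 + (cols - anchors[k, 2])^2
    }
    matrix(apply(d, c(1, 2), which.min), grid$n_rows, grid$n_cols)
  })
}
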