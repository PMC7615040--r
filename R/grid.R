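#' @importFrom stats rnorm runif sd quantile glm binomial plogis predict
#'   complete.cases
#' @importFrom utils read.csv write.csv
NULL

# Shared georeferencing for all grid-shaped objects.
#
# A grid covers the rectangle [origin_lon, origin_lon + n_cols*cell_size] x
# [origin_lat, origin_lat + n_rows*cell_size] in WGS84 degrees, with the
# origin at the lower-left corner. Matrices are stored with row 1 as the
# NORTHERNMOST row (the usual raster convention), so matrix[r, c] is the cell
# whose centre is at
#   lon = origin_lon + (c - 0.5) * cell_size
#   lat = origin_lat + (n_rows - r + 0.5) * cell_size

new_georef <- function(origin_lon, origin_lat, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat),
            cell_size > 0, n_rows >= 1, n_cols >= 1)
  list(origin_lon = as.numeric(origin_lon),
       origin_lat = as.numeric(origin_lat),
       cell_size  = as.numeric(cell_size),
       n_rows     = as.integer(n_rows),
       n_cols     = as.integer(n_cols))
}

georef <- function(x) {
  x[c("origin_lon", "origin_lat", "cell_size", "n_rows", "n_cols")]
}

same_georef <- function(a, b, tol = 1e-9) {
  ga <- georef(a); gb <- georef(b)
  ga$n_rows == gb$n_rows && ga$n_cols == gb$n_cols &&
    abs(ga$origin_lon - gb$origin_lon) < tol &&
    abs(ga$origin_lat - gb$origin_lat) < tol &&
    abs(ga$cell_size - gb$cell_size) < tol
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_georef(a, b)) {
    stop(sprintf("misaligned %s: georeferencing differs", what), call. = FALSE)
  }
  invisible(TRUE)
}

# Latitude of the centre of matrix row r (1 = northernmost).
row_center_lat <- function(g, r) {
  g$origin_lat + (g$n_rows - r + 0.5) * g$cell_size
}

col_center_lon <- function(g, c) {
  g$origin_lon + (c - 0.5) * g$cell_size
}

#' Map lon/lat points to grid row/column indices
#'
#' Points exactly on the upper/right boundary are assigned to the last
#' row/column. Points outside the grid get `NA` indices.
#'
#' @param g an object carrying grid georeferencing (a [climate_grid] or
#'   [suitability_raster]).
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @return a data.frame with integer columns `row` and `col` (`NA` off-grid).
#' @export
cell_index <- function(g, lon, lat) {
  gg <- georef(g)
  cs <- gg$cell_size
  col <- floor((lon - gg$origin_lon) / cs) + 1L
  row_from_bottom <- floor((lat - gg$origin_lat) / cs) + 1L
  # fold boundary points back onto the grid
  on_right <- !is.na(lon) & lon == gg$origin_lon + gg$n_cols * cs
  on_top   <- !is.na(lat) & lat == gg$origin_lat + gg$n_rows * cs
  col[on_right] <- gg$n_cols
  row_from_bottom[on_top] <- gg$n_rows
  bad <- is.na(lon) | is.na(lat) |
    col < 1L | col > gg$n_cols | row_from_bottom < 1L | row_from_bottom > gg$n_rows
  row <- gg$n_rows - row_from_bottom + 1L
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Construct a multi-layer bioclimatic grid
#'
#' Container for one scenario's climate layers on a regular lon/lat grid.
#' The six canonical layers are bio1 (mean annual temperature, deg C), bio5
#' (max temperature of the warmest month), bio6 (min temperature of the
#' coldest month), bio12 (annual precipitation, mm), bio13 (precipitation of
#' the wettest month) and bio14 (precipitation of the driest month).
#'
#' @param origin_lon,origin_lat lower-left corner, degrees.
#' @param cell_size cell edge in degrees (2 arcmin = 1/30 by default usage).
#' @param layers named list of equal-dimension numeric matrices.
#' @param scenario_tag label, e.g. `"present"` or `"rcp45_2080"`.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(origin_lon, origin_lat, cell_size, layers,
                         scenario_tag = "present") {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share identical dimensions", call. = FALSE)
  }
  g <- new_georef(origin_lon, origin_lat, cell_size, dims[1, 1], dims[2, 1])
  g$layers <- layers
  g$scenario_tag <- scenario_tag
  class(g) <- "climate_grid"
  g
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %dx%d cells of %.5f deg, scenario '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$scenario_tag))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

bioclim_vars <- function() c("bio1", "bio5", "bio6", "bio12", "bio13", "bio14")

check_climate_invariants <- function(g) {
  stopifnot(inherits(g, "climate_grid"))
  vars <- bioclim_vars()
  missing <- setdiff(vars, names(g$layers))
  if (length(missing)) {
    stop("climate grid lacks layers: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) {
    if (!all(is.finite(g$layers[[v]]))) stop("non-finite values in ", v)
  }
  for (v in c("bio12", "bio13", "bio14")) {
    if (any(g$layers[[v]] < 0)) stop("negative precipitation in ", v)
  }
  if (any(g$layers$bio5 < g$layers$bio1) || any(g$layers$bio1 < g$layers$bio6)) {
    stop("temperature ordering violated: need bio5 >= bio1 >= bio6 cell-wise")
  }
  invisible(TRUE)
}

#' Construct a habitat-suitability raster
#'
#' Per-cell occurrence probability in \[0, 1\] aligned to a climate grid.
#' `NA` cells are masked. The same container carries SDM outputs, network
#' priors and network posteriors; `source` records which.
#'
#' @param g a `climate_grid` (or anything with the same georeferencing) the
#'   raster is aligned to.
#' @param values numeric matrix in \[0,1\] (NA = masked).
#' @param species_id species label.
#' @param source one of the algorithm names, `"ensemble"` or `"posterior"`.
#' @param scenario_tag scenario label, copied from the grid by default.
#' @return an object of class `suitability_raster`.
#' @export
suitability_raster <- function(g, values, species_id = NA_character_,
                               source = "manual",
                               scenario_tag = NULL) {
  gg <- georef(g)
  values <- as.matrix(values)
  if (!all(dim(values) == c(gg$n_rows, gg$n_cols))) {
    stop("values matrix does not match grid dimensions", call. = FALSE)
  }
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  out <- gg
  out$values <- pmin(pmax(values, 0), 1)
  out$species_id <- species_id
  out$source <- source
  out$scenario_tag <- if (is.null(scenario_tag)) {
    if (!is.null(g$scenario_tag)) g$scenario_tag else NA_character_
  } else scenario_tag
  class(out) <- "suitability_raster"
  out
}

#' @export
print.suitability_raster <- function(x, ...) {
  cat(sprintf("<suitability_raster> %s/%s/%s %dx%d, range [%.3f, %.3f]\n",
              x$species_id, x$source, x$scenario_tag, x$n_rows, x$n_cols,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Construct a binary presence/absence map
#'
#' @param g object carrying georeferencing.
#' @param presence logical matrix (NA = masked).
#' @param threshold_value the score at/above which a cell is present.
#' @param rule `"TSS"`, `"Prevalence"` or `"manual"`.
#' @return an object of class `binary_map`.
#' @export
binary_map <- function(g, presence, threshold_value = NA_real_,
                       rule = "manual") {
  gg <- georef(g)
  presence <- as.matrix(presence)
  if (!all(dim(presence) == c(gg$n_rows, gg$n_cols))) {
    stop("presence matrix does not match grid dimensions", call. = FALSE)
  }
  out <- gg
  out$presence <- matrix(as.logical(presence), gg$n_rows, gg$n_cols)
  out$threshold_value <- threshold_value
  out$rule <- rule
  out$scenario_tag <- if (!is.null(g$scenario_tag)) g$scenario_tag else NA_character_
  class(out) <- "binary_map"
  out
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %dx%d, rule %s at %.4g, %d present cells\n",
              x$n_rows, x$n_cols, x$rule, x$threshold_value,
              sum(x$presence, na.rm = TRUE)))
  invisible(x)
}

#' Extract layer values at point locations
#'
#' @param grid a `climate_grid`.
#' @param lon,lat point coordinates in degrees.
#' @return matrix with one row per point and one column per layer; `NA`
#'   rows for off-grid points.
#' @export
extract_climate <- function(grid, lon, lat) {
  idx <- cell_index(grid, lon, lat)
  out <- sapply(grid$layers, function(m) {
    v <- rep(NA_real_, nrow(idx))
    ok <- !is.na(idx$row)
    v[ok] <- m[cbind(idx$row[ok], idx$col[ok])]
    v
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = length(lon),
                                       dimnames = list(NULL, names(grid$layers)))
  out
}

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# RNG so generators stay pure functions of (seed, parameters).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: stage/species-specific streams from one
# master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) utf8ToInt(as.character(p))))
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) h <- (h * 131 + p) %% 2147483647
  as.integer(h)
}
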