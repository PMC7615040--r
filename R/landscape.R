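# Thresholding continuous suitability into binary habitat (TSS and
# prevalence rules) and landscape summaries: spherical habitat area, patch
# counts and density under queen adjacency, and percent change by scenario
# and region.

threshold_result <- function(threshold, stat, sens, spec, rule) {
  structure(list(threshold = threshold, stat = stat,
                 sensitivity = sens, specificity = spec, rule = rule),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s t=%.4g stat=%.4g sens=%.3f spec=%.3f\n",
              x$rule, x$threshold, x$stat, x$sensitivity, x$specificity))
  invisible(x)
}

eval_scores <- function(suitability, presences, background) {
  sp <- extract_suitability(suitability, presences)
  sb <- extract_suitability(suitability, background)
  if (!length(sp) || !length(sb)) {
    stop("both evaluation point sets must be non-empty", call. = FALSE)
  }
  if (anyNA(sp) || anyNA(sb)) {
    stop("evaluation points fall on masked cells", call. = FALSE)
  }
  list(p = sp, b = sb)
}

#' Maximum-TSS threshold
#'
#' Scans every unique score among the evaluation points as a candidate
#' threshold (presence predicted iff score >= t) and returns the one
#' maximising the True Skill Statistic, sensitivity + specificity - 1,
#' which is insensitive to prevalence. Ties go to the smallest threshold.
#'
#' @param suitability a [suitability_raster].
#' @param presences,background evaluation point tables.
#' @return a `threshold_result` with fields `threshold`, `stat` (the TSS),
#'   `sensitivity`, `specificity`.
#' @export
tss_threshold <- function(suitability, presences, background) {
  s <- eval_scores(suitability, presences, background)
  cand <- sort(unique(c(s$p, s$b)))
  sens <- vapply(cand, function(t) mean(s$p >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(s$b < t), numeric(1))
  tss <- sens + spec - 1
  i <- which(tss == max(tss))[1]  # candidates ascending, so first = smallest t
  threshold_result(cand[i], tss[i], sens[i], spec[i], "TSS")
}

#' Prevalence-matching threshold
#'
#' Picks the candidate threshold at which the fraction of evaluation points
#' predicted present best matches the observed prevalence
#' `n_presence / (n_presence + n_background)`; typically less restrictive
#' than the TSS threshold. Ties go to the smallest threshold.
#'
#' @inheritParams tss_threshold
#' @return a `threshold_result` (`stat` is the achieved |fraction -
#'   prevalence| gap).
#' @export
prevalence_threshold <- function(suitability, presences, background) {
  s <- eval_scores(suitability, presences, background)
  all_sc <- c(s$p, s$b)
  prev <- length(s$p) / length(all_sc)
  cand <- sort(unique(all_sc))
  gap <- vapply(cand, function(t) abs(mean(all_sc >= t) - prev), numeric(1))
  i <- which(gap == min(gap))[1]
  t <- cand[i]
  threshold_result(t, gap[i],
                   mean(s$p >= t), mean(s$b < t), "Prevalence")
}

#' Threshold a suitability raster into a binary habitat map
#'
#' @param suitability a [suitability_raster].
#' @param t threshold in \[0, 1\]; cells with score >= t are present.
#' @param rule label recorded on the map.
#' @return a [binary_map]; masked cells stay masked.
#' @export
binarize <- function(suitability, t, rule = "manual") {
  stopifnot(t >= 0, t <= 1)
  binary_map(suitability, suitability$values >= t, threshold_value = t,
             rule = rule)
}

EARTH_RADIUS_KM <- 6371

#' Spherical area of a grid cell at a given latitude
#'
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with R = 6371 km: the
#' exact area of a lon/lat quadrangle on the sphere. A 2-arcmin cell on the
#' equator is about 13.74 km^2.
#'
#' @param lat_center cell-centre latitude in degrees.
#' @param cell_size cell edge in degrees.
#' @return area in km^2 (vectorised over `lat_center`).
#' @export
cell_area <- function(lat_center, cell_size) {
  half <- cell_size / 2
  dl <- cell_size * pi / 180
  EARTH_RADIUS_KM^2 * dl *
    (sin((lat_center + half) * pi / 180) - sin((lat_center - half) * pi / 180))
}

#' Total habitat area of a binary map
#'
#' Sum of spherical cell areas over present cells.
#'
#' @param map a [binary_map].
#' @param region optional logical matrix restricting the sum.
#' @return area in thousands of km^2.
#' @export
habitat_area <- function(map, region = NULL) {
  pres <- map$presence
  pres[is.na(pres)] <- FALSE
  if (!is.null(region)) pres <- pres & region
  row_areas <- cell_area(row_center_lat(map, seq_len(map$n_rows)),
                         map$cell_size)
  sum(rowSums(pres) * row_areas) / 1000
}

# Adjacency offsets for patch connectivity.
neighbour_offsets <- function(adjacency) {
  if (adjacency == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
}

#' Label connected habitat patches
#'
#' Connected components of present cells under queen (8-neighbour, the
#' landscape-ecology default) or rook (4-neighbour) adjacency, computed via
#' the adjacency graph's components.
#'
#' @param map a [binary_map].
#' @param adjacency `"queen"` or `"rook"`.
#' @return integer matrix of patch labels (NA where absent).
#' @export
label_patches <- function(map, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  pres <- map$presence
  pres[is.na(pres)] <- FALSE
  lab <- matrix(NA_integer_, map$n_rows, map$n_cols)
  cells <- which(pres)
  if (!length(cells)) return(lab)
  id <- matrix(0L, map$n_rows, map$n_cols)
  id[cells] <- seq_along(cells)
  off <- neighbour_offsets(adjacency)
  rc <- arrayInd(cells, dim(pres))
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    r2 <- rc[, 1] + off[k, 1]; c2 <- rc[, 2] + off[k, 2]
    ok <- r2 >= 1 & r2 <= map$n_rows & c2 >= 1 & c2 <= map$n_cols
    ok[ok] <- pres[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges <- rbind(edges, cbind(id[cells[ok]], id[cbind(r2[ok], c2[ok])]))
    }
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[cells] <- as.integer(comp)
  lab
}

#' Patch count and patch density
#'
#' Density is the number of patches per 1000 km^2 of suitable habitat
#' (denominator = habitat area, as in fragmentation reporting; set
#' `denominator = "study_area"` to use the whole-grid area instead).
#'
#' @param map a [binary_map].
#' @param adjacency `"queen"` or `"rook"`.
#' @param denominator `"habitat"` or `"study_area"`.
#' @return list with `patch_count` and `density` (NA when there is no
#'   habitat).
#' @export
patch_density <- function(map, adjacency = "queen",
                          denominator = c("habitat", "study_area")) {
  denominator <- match.arg(denominator)
  lab <- label_patches(map, adjacency)
  n_patch <- if (all(is.na(lab))) 0L else max(lab, na.rm = TRUE)
  if (n_patch == 0L) return(list(patch_count = 0L, density = NA_real_))
  area <- if (denominator == "habitat") {
    habitat_area(map)
  } else {
    all_map <- binary_map(map, matrix(TRUE, map$n_rows, map$n_cols))
    habitat_area(all_map)
  }
  list(patch_count = n_patch, density = n_patch / area)
}

#' Percent change, rounded half away from zero
#'
#' `100 * (after - before) / before`, rounded to a signed integer with
#' halves away from zero (so -56.5 becomes -57, not -56).
#'
#' @param before,after positive baseline and new value (areas or
#'   densities).
#' @return signed integer percent (NA when `before` is 0).
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) {
    warning("percent change undefined for zero baseline")
  }
  x <- 100 * (after - before) / before
  out <- sign(x) * floor(abs(x) + 0.5)
  out[before == 0] <- NA_real_
  out
}

#' Landscape report across scenarios and regions
#'
#' Per scenario x region (a whole-grid "total" region is always included):
#' habitat area in '000 km^2, patch count, patch density per 1000 km^2 of
#' habitat, and integer percent change of area versus the present scenario.
#'
#' @param maps named list of [binary_map]s; must include `present`.
#' @param regions optional integer matrix of region labels (grid-shaped).
#' @param region_names optional names for the region labels.
#' @param adjacency patch adjacency rule.
#' @return data.frame with columns `scenario`, `region`,
#'   `area_thousand_km2`, `patch_count`, `patch_density`, `percent_change`.
#' @export
landscape_report <- function(maps, regions = NULL, region_names = NULL,
                             adjacency = "queen") {
  if (!"present" %in% names(maps)) {
    stop("maps must include a 'present' scenario", call. = FALSE)
  }
  for (m in maps[-1]) stop_if_misaligned(maps[[1]], m, "binary maps")
  region_masks <- list(total = NULL)
  if (!is.null(regions)) {
    labs <- sort(unique(as.vector(regions)))
    nm <- if (is.null(region_names)) paste0("region_", labs) else region_names
    for (i in seq_along(labs)) region_masks[[nm[i]]] <- regions == labs[i]
  }
  rows <- list()
  for (rg in names(region_masks)) {
    mask <- region_masks[[rg]]
    base <- habitat_area(maps$present, mask)
    for (sc in names(maps)) {
      m <- maps[[sc]]
      if (!is.null(mask)) {
        pres <- m$presence & mask
        m <- binary_map(m, pres, m$threshold_value, m$rule)
      }
      pd <- patch_density(m, adjacency)
      a <- habitat_area(m)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, region = rg,
        area_thousand_km2 = a,
        patch_count = pd$patch_count,
        patch_density = pd$density,
        percent_change = if (base > 0) percent_change(base, a) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
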