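# Occurrence ingestion and cleaning: basis-of-record filtering, coordinate
# validity tests against a gazetteer and land mask, rarefaction to one
# record per grid cell, and the minimum-record rule for model fitting.

DEFAULT_BASIS <- c("HUMAN_OBSERVATION", "LIVING_SPECIMEN",
                   "MACHINE_OBSERVATION")

#' Keep only records with an accepted basis of record
#'
#' @param records occurrence data.frame (`species`, `decimalLongitude`,
#'   `decimalLatitude`, `basisOfRecord`).
#' @param allowed character vector of accepted classes; the default is the
#'   standard trio of human observation, living specimen and machine
#'   observation.
#' @return the subset of `records`, input order preserved.
#' @export
filter_basis <- function(records, allowed = DEFAULT_BASIS) {
  stopifnot(is.data.frame(records))
  records[records$basisOfRecord %in% allowed, , drop = FALSE]
}

#' Flag species with too few records to model
#'
#' Applied after cleaning and rarefaction, so the count reflects the data a
#' model would actually be fitted on.
#'
#' @param records cleaned, rarefied occurrence data.frame.
#' @param min_n minimum record count (default 20; fewer records inflate
#'   model error and starve k-fold cross-validation).
#' @return data.frame with columns `species`, `n_records`, `retained`.
#' @export
require_min_records <- function(records, min_n = 20) {
  stopifnot(min_n >= 1)
  if (nrow(records) == 0) {
    return(data.frame(species = character(0), n_records = integer(0),
                      retained = logical(0)))
  }
  tab <- as.data.frame(table(species = records$species),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "n_records"
  tab$retained <- tab$n_records >= min_n
  tab
}

#' Clean occurrence records against coordinate-error tests
#'
#' Removes records that fail any of: exact match to a capital or country
#' centroid gazetteer point; equal longitude and latitude; within
#' `buffer_deg` degrees (plain Euclidean in degree space) of a biodiversity
#' institution; falling in a sea cell of the land mask; plain-zero
#' coordinates; or lying outside the analysis grid / valid lon-lat range.
#' A record may fail several tests (each is tallied) but is removed once.
#'
#' @param records occurrence data.frame.
#' @param gazetteer data.frame `name`, `type` (capital / centroid /
#'   institution), `lon`, `lat`.
#' @param land_mask a [binary_map] aligned to the analysis grid
#'   (TRUE = land).
#' @param buffer_deg institution buffer radius in degrees (default 1).
#' @return list with `records` (retained rows, order preserved) and
#'   `report` (class `cleaning_report`: per-test removal counts,
#'   `total_removed`, `total_retained`, `input_rows`).
#' @export
clean_records <- function(records, gazetteer, land_mask, buffer_deg = 1.0) {
  stopifnot(is.data.frame(records), is.data.frame(gazetteer),
            inherits(land_mask, "binary_map"))
  n <- nrow(records)
  lon <- records$decimalLongitude
  lat <- records$decimalLatitude

  out_of_range <- is.na(lon) | is.na(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  idx <- cell_index(land_mask, lon, lat)
  off_grid <- is.na(idx$row)
  out_of_range <- out_of_range | off_grid

  capcent <- gazetteer[gazetteer$type %in% c("capital", "centroid"), ]
  cap_hit <- rep(FALSE, n)
  if (nrow(capcent)) {
    # exact coordinate equality at full stored precision
    key <- paste(lon, lat)
    cap_hit <- key %in% paste(capcent$lon, capcent$lat)
  }

  eq_hit <- !is.na(lon) & !is.na(lat) & lon == lat

  inst <- gazetteer[gazetteer$type == "institution", ]
  inst_hit <- rep(FALSE, n)
  if (nrow(inst)) {
    for (i in seq_len(nrow(inst))) {
      d2 <- (lon - inst$lon[i])^2 + (lat - inst$lat[i])^2
      inst_hit <- inst_hit | (!is.na(d2) & d2 <= buffer_deg^2)
    }
  }

  sea_hit <- rep(FALSE, n)
  ok <- !off_grid
  sea_hit[ok] <- !land_mask$presence[cbind(idx$row[ok], idx$col[ok])]

  zero_hit <- !is.na(lon) & !is.na(lat) & lon == 0 & lat == 0

  fail <- cap_hit | eq_hit | inst_hit | sea_hit | zero_hit | out_of_range
  report <- structure(list(
    capital_centroid = sum(cap_hit),
    equal_lonlat = sum(eq_hit),
    institution = sum(inst_hit),
    sea = sum(sea_hit),
    zeros = sum(zero_hit),
    out_of_range = sum(out_of_range),
    total_removed = sum(fail),
    total_retained = sum(!fail),
    input_rows = n), class = "cleaning_report")
  list(records = records[!fail, , drop = FALSE], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  for (k in names(x)) cat(sprintf("  %-17s %d\n", k, x[[k]]))
  invisible(x)
}

#' Rarefy records to one per grid cell per species
#'
#' Deterministic tie-break: the first record in input order for each
#' occupied cell is kept.
#'
#' @param records cleaned occurrence data.frame (all rows must fall on the
#'   grid).
#' @param grid a [climate_grid] (or any georeferenced object).
#' @return the rarefied data.frame, input order preserved.
#' @export
rarefy <- function(records, grid) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  idx <- cell_index(grid, records$decimalLongitude, records$decimalLatitude)
  if (anyNA(idx$row)) {
    stop("off-grid records present; clean before rarefying", call. = FALSE)
  }
  key <- paste(records$species, idx$row, idx$col)
  records[!duplicated(key), , drop = FALSE]
}
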