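# Plain-text serialization: ESRI ASCII grids for rasters, CSV for
# occurrences / gazetteers / edge lists / reports, key=value text for
# cleaning reports, YAML for pipeline configs.

#' Write a grid-shaped object as an ESRI ASCII raster
#'
#' @param x a [suitability_raster], [binary_map], or a plain matrix (then
#'   `g` must supply georeferencing).
#' @param path output file path (.asc).
#' @param g georeferenced object when `x` is a bare matrix.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(x, path, g = NULL, nodata = -9999) {
  if (is.matrix(x)) {
    stopifnot(!is.null(g))
    vals <- x
    gg <- georef(g)
  } else if (inherits(x, "binary_map")) {
    vals <- x$presence * 1L
    gg <- georef(x)
  } else {
    vals <- x$values
    gg <- georef(x)
  }
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", gg$n_cols),
               sprintf("nrows %d", gg$n_rows),
               sprintf("xllcorner %.10g", gg$origin_lon),
               sprintf("yllcorner %.10g", gg$origin_lat),
               sprintf("cellsize %.10g", gg$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(vals, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path .asc file path.
#' @return list with `values` (matrix, row 1 = north), `origin_lon`,
#'   `origin_lat`, `cell_size`, `n_rows`, `n_cols`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA
  c(new_georef(val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]],
               val[["nrows"]], val[["ncols"]]),
    list(values = m))
}

#' Read a suitability raster from an ESRI ASCII grid
#' @param path .asc file path.
#' @param species_id,source,scenario_tag provenance labels.
#' @return a [suitability_raster].
#' @export
read_suitability <- function(path, species_id = NA_character_,
                             source = "file", scenario_tag = NA_character_) {
  g <- read_ascii_grid(path)
  g$scenario_tag <- scenario_tag
  suitability_raster(g, g$values, species_id = species_id, source = source,
                     scenario_tag = scenario_tag)
}

#' Write / read occurrence tables
#'
#' CSV with the standard columns `species`, `decimalLongitude`,
#' `decimalLatitude`, `basisOfRecord`.
#'
#' @param records occurrence data.frame.
#' @param path CSV path.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a signed interaction edge list
#'
#' CSV with columns `parent`, `child`, `sign` (+/-), `subnetwork_order`.
#'
#' @param path CSV path.
#' @param focal focal species label.
#' @return an [interaction_network].
#' @export
read_network <- function(path, focal) {
  interaction_network(utils::read.csv(path, stringsAsFactors = FALSE), focal)
}

#' @rdname read_network
#' @param network an [interaction_network] to serialize.
#' @export
write_network <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a cleaning report as flat key=value text
#' @param report a `cleaning_report`.
#' @param path output path.
#' @export
write_cleaning_report <- function(report, path) {
  writeLines(sprintf("%s=%d", names(report), unlist(report)), path)
  invisible(path)
}

#' Write cross-validation summaries as CSV
#'
#' One row per (algorithm, fold) plus a `summary` row per algorithm with the
#' mean and sd.
#'
#' @param cv named list of `cv_summary` objects (names = algorithms).
#' @param path CSV path.
#' @export
write_cv_table <- function(cv, path) {
  rows <- do.call(rbind, lapply(names(cv), function(a) {
    s <- cv[[a]]
    rbind(data.frame(algorithm = a, fold = seq_len(s$k), auc = s$fold_auc),
          data.frame(algorithm = a, fold = "mean", auc = s$mean_auc),
          data.frame(algorithm = a, fold = "sd", auc = s$sd_auc))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$network$edges)) {
    cfg$network$edges <- as.data.frame(
      do.call(rbind, lapply(cfg$network$edges, as.data.frame)))
  }
  cfg
}

#' @rdname read_config
#' @param config a pipeline config list.
#' @export
write_config <- function(config, path) {
  if (is.data.frame(config$network$edges)) {
    config$network$edges <- lapply(
      seq_len(nrow(config$network$edges)),
      function(i) as.list(config$network$edges[i, ]))
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
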