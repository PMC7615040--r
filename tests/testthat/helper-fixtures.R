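# Shared fixtures and independent oracles, all built in code.

# A small climate grid with explicitly chosen layers (constant except where
# a test injects structure), for controlled SDM behaviour.
flat_grid <- function(n_rows = 4, n_cols = 5, bio1 = 22,
                      origin_lon = 20, origin_lat = -25, cell_size = 0.25) {
  const <- function(v) matrix(v, n_rows, n_cols)
  climate_grid(origin_lon, origin_lat, cell_size,
               layers = list(bio1 = const(bio1), bio5 = const(bio1 + 9),
                             bio6 = const(bio1 - 11), bio12 = const(450),
                             bio13 = const(110), bio14 = const(10)))
}

# A grid whose bio1 varies linearly across columns; other variables flat.
gradient_grid <- function(n_rows = 2, n_cols = 100, from = 10, to = 34,
                          cell_size = 0.02) {
  g <- flat_grid(n_rows, n_cols, cell_size = cell_size)
  g$layers$bio1 <- matrix(rep(seq(from, to, length.out = n_cols),
                              each = n_rows), n_rows, n_cols)
  g$layers$bio5 <- g$layers$bio1 + 9
  g$layers$bio6 <- g$layers$bio1 - 11
  g
}

# Wrap a bare matrix of probabilities as a suitability raster on any grid.
suit_from_matrix <- function(m, g = NULL) {
  if (is.null(g)) g <- flat_grid(nrow(m), ncol(m))
  suitability_raster(g, m)
}

# Species whose niche is centred on a flat grid's climate.
centered_species <- function(g, breadth_t = 2.5, max_prob = 0.95,
                             id = "sp") {
  mid <- vapply(g$layers, function(m) m[1, 1], numeric(1))
  virtual_species(id,
                  niche_optimum = mid,
                  niche_breadth = c(bio1 = breadth_t, bio5 = breadth_t * 1.3,
                                    bio6 = breadth_t * 1.3, bio12 = 200,
                                    bio13 = 60, bio14 = 8),
                  max_prob = max_prob)
}

# Lag-1 spatial autocorrelation of a matrix (average of the row-lag and
# column-lag Pearson correlations) - independent check of the smoother.
lag1_autocor <- function(m) {
  r <- cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  c2 <- cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  mean(c(r, c2))
}

# Brute-force flood-fill patch labelling, the independent oracle for
# label_patches().
floodfill_patches <- function(pres, queen = TRUE) {
  pres[is.na(pres)] <- FALSE
  lab <- matrix(NA_integer_, nrow(pres), ncol(pres))
  nxt <- 0L
  offs <- if (queen) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (r0 in seq_len(nrow(pres))) for (c0 in seq_len(ncol(pres))) {
    if (!pres[r0, c0] || !is.na(lab[r0, c0])) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- cur[1] + o[1]; c <- cur[2] + o[2]
        if (r >= 1 && r <= nrow(pres) && c >= 1 && c <= ncol(pres) &&
            pres[r, c] && is.na(lab[r, c])) {
          lab[r, c] <- nxt
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  lab
}

# Scalar wrappers around resolve(): a 1x1 raster per probability, so the
# closed form can be compared cell-free against the enumeration oracle.
one_cell_grid <- function() flat_grid(n_rows = 1, n_cols = 1)
scalar_raster <- function(v, g = one_cell_grid()) {
  suit_from_matrix(matrix(v, 1, 1), g)
}
resolve_scalar <- function(p, parents, cfg) {
  pl <- lapply(parents, function(pa) {
    list(raster = scalar_raster(pa$q), sign = pa$sign)
  })
  resolve(scalar_raster(p), pl, cfg)$values[1, 1]
}

# One shared demo-pipeline run, computed lazily and reused across tests.
.demo_cache <- new.env(parent = emptyenv())
demo_art <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.demo_cache[[key]])) {
    .demo_cache[[key]] <- suppressWarnings(run_all(demo_config(), seed = seed))
  }
  .demo_cache[[key]]
}
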