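pt <- function(lon, lat) data.frame(lon = lon, lat = lat)

# Suitability raster over a 2x2 grid whose four cells score the four given
# values; evaluation points sit at the cell centres.
four_cell <- function(scores) {
  g <- flat_grid(n_rows = 2, n_cols = 2)
  r <- suit_from_matrix(matrix(scores, 2, 2), g)
  centres <- expand.grid(row = 1:2, col = 1:2)
  pts <- pt(bnsdm:::col_center_lon(g, centres$col),
            bnsdm:::row_center_lat(g, centres$row))
  list(raster = r, points = pts)
}

test_that("TSS threshold maximises sensitivity + specificity - 1", {
  fx <- four_cell(c(0.8, 0.6, 0.3, 0.7))
  res <- tss_threshold(fx$raster, fx$points[1:2, ], fx$points[3:4, ])
  expect_equal(res$threshold, 0.6)
  expect_equal(res$stat, 0.5)
  # perfectly separated: TSS = 1 at the smallest candidate in the gap
  fx2 <- four_cell(c(0.9, 0.8, 0.1, 0.2))
  res2 <- tss_threshold(fx2$raster, fx2$points[1:2, ], fx2$points[3:4, ])
  expect_equal(res2$stat, 1)
  expect_equal(res2$threshold, 0.8)
  # identical score distributions: no skill
  fx3 <- four_cell(c(0.5, 0.5, 0.5, 0.5))
  res3 <- tss_threshold(fx3$raster, fx3$points[1:2, ], fx3$points[3:4, ])
  expect_equal(res3$stat, 0)
})

test_that("prevalence threshold matches the predicted-present fraction", {
  fx <- four_cell(c(0.9, 0.7, 0.1, 0.3))
  # one presence, three background: prevalence 0.25 -> only the top point
  res <- prevalence_threshold(fx$raster, fx$points[1, , drop = FALSE],
                              fx$points[2:4, ])
  expect_equal(res$threshold, 0.9)
  expect_equal(res$stat, 0)
  # single presence vs single background, scores 0.9 / 0.1: t = 0.9
  fx2 <- four_cell(c(0.9, 0.1, 0.9, 0.1))
  res2 <- prevalence_threshold(fx2$raster, fx2$points[1, , drop = FALSE],
                               fx2$points[2, , drop = FALSE])
  expect_equal(res2$threshold, 0.9)
})

test_that("binarization respects threshold, mask, and idempotence", {
  g <- flat_grid(n_rows = 2, n_cols = 3)
  vals <- matrix(c(0.1, 0.4, 0.6, NA, 0.9, 0.2), 2, 3)
  r <- suitability_raster(g, vals)
  b0 <- binarize(r, 0)
  expect_equal(sum(b0$presence, na.rm = TRUE), 5)  # all unmasked present
  b_hi <- binarize(r, 0.95)
  expect_equal(sum(b_hi$presence, na.rm = TRUE), 0)
  expect_true(is.na(b_hi$presence[2, 2]))
  b <- binarize(r, 0.4)
  expect_identical(binarize(suitability_raster(g, b$presence * 1), 1)$presence,
                   b$presence)
  # lower thresholds give supersets
  for (t_pair in list(c(0.2, 0.5), c(0.1, 0.9))) {
    lo <- binarize(r, t_pair[1])$presence
    hi <- binarize(r, t_pair[2])$presence
    expect_true(all(lo[hi], na.rm = TRUE))
  }
})

test_that("spherical cell areas match closed-form checks", {
  # 2-arcmin cell centred on the equator
  expect_equal(cell_area(0, 1 / 30), 13.74, tolerance = 0.01 / 13.74)
  # strictly decreasing with |latitude|
  lats <- seq(0, 80, by = 10)
  a <- cell_area(lats, 1 / 30)
  expect_true(all(diff(a) < 0))
  expect_equal(cell_area(-45, 1 / 30), cell_area(45, 1 / 30))
  # whole-sphere sum of 1-degree bands = 4 pi R^2
  bands <- cell_area(seq(-89.5, 89.5, by = 1), 1) * 360
  expect_equal(sum(bands), 4 * pi * 6371^2, tolerance = 1e-3)
})

test_that("habitat area sums present-cell areas and is additive", {
  g <- flat_grid(n_rows = 2, n_cols = 2, origin_lat = -1 / 30,
                 cell_size = 1 / 30)
  pres <- matrix(FALSE, 2, 2)
  expect_equal(habitat_area(binary_map(g, pres)), 0)
  pres[2, 1] <- TRUE  # cell centred just north of the equator
  a1 <- habitat_area(binary_map(g, pres))
  expect_equal(a1, 0.01374, tolerance = 1e-3)
  pres2 <- matrix(FALSE, 2, 2); pres2[1, 2] <- TRUE
  both <- pres | pres2
  expect_equal(habitat_area(binary_map(g, both)),
               a1 + habitat_area(binary_map(g, pres2)))
})

test_that("patch labelling follows the chosen adjacency", {
  g <- flat_grid(n_rows = 4, n_cols = 4)
  diagonal <- matrix(FALSE, 4, 4)
  diagonal[1, 1] <- diagonal[2, 2] <- TRUE
  expect_equal(patch_density(binary_map(g, diagonal))$patch_count, 1)
  expect_equal(patch_density(binary_map(g, diagonal),
                             adjacency = "rook")$patch_count, 2)
  checker <- outer(1:4, 1:4, function(r, c) (r + c) %% 2 == 0)
  expect_equal(patch_density(binary_map(g, checker))$patch_count, 1)
  empty <- patch_density(binary_map(g, matrix(FALSE, 4, 4)))
  expect_equal(empty$patch_count, 0)
  expect_true(is.na(empty$density))
})

test_that("patch labelling agrees with the flood-fill oracle", {
  g <- flat_grid(n_rows = 10, n_cols = 10)
  set.seed(101)
  for (rep in 1:50) {
    pres <- matrix(runif(100) < runif(1, 0.2, 0.7), 10, 10)
    m <- binary_map(g, pres)
    for (adj in c("queen", "rook")) {
      got <- label_patches(m, adj)
      want <- floodfill_patches(pres, queen = adj == "queen")
      expect_equal(max(c(got, 0L), na.rm = TRUE),
                   max(c(want, 0L), na.rm = TRUE))
      # identical partition, not just identical counts
      expect_true(all(is.na(got) == is.na(want)))
      if (any(!is.na(got))) {
        expect_equal(length(unique(paste(got, want)[!is.na(got)])),
                     max(got, na.rm = TRUE))
      }
    }
  }
})

test_that("patch density divides count by habitat area", {
  g <- flat_grid(n_rows = 3, n_cols = 3)
  pres <- matrix(FALSE, 3, 3)
  pres[1, 1] <- pres[3, 3] <- pres[1, 3] <- TRUE
  m <- binary_map(g, pres)
  pd <- patch_density(m)
  expect_equal(pd$patch_count, 3)
  expect_equal(pd$density, 3 / habitat_area(m))
  pd2 <- patch_density(m, denominator = "study_area")
  all_area <- habitat_area(binary_map(g, matrix(TRUE, 3, 3)))
  expect_equal(pd2$density, 3 / all_area)
})

test_that("percent change is integer, signed and half-away-from-zero", {
  expect_equal(percent_change(649, 285), -56)
  expect_equal(percent_change(1480, 905), -39)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(200, 301), 51)   # 50.5 rounds away from zero
  expect_equal(percent_change(200, 99), -51)   # -50.5 likewise
  # sign anti-symmetry in (after - before)
  expect_equal(percent_change(100, 130), -percent_change(100, 70))
  expect_gt(percent_change(100, 150), 0)
  expect_lt(percent_change(150, 100), 0)
  expect_warning(out <- percent_change(0, 5), "zero baseline")
  expect_true(is.na(out))
})

test_that("landscape report partitions area over regions", {
  g <- flat_grid(n_rows = 6, n_cols = 6)
  set.seed(55)
  present <- binarize(suit_from_matrix(matrix(runif(36), 6, 6), g), 0.4)
  future <- binarize(suit_from_matrix(present$presence * 0.1, g), 0.05)
  maps <- list(present = present, future = future)
  regions <- matrix(rep(c(1, 2), each = 18), 6, 6)
  rep_tab <- landscape_report(maps, regions)
  tot <- rep_tab[rep_tab$region == "total", ]
  expect_equal(tot$percent_change[tot$scenario == "present"], 0)
  by_region <- rep_tab[rep_tab$region != "total", ]
  for (sc in c("present", "future")) {
    expect_equal(sum(by_region$area_thousand_km2[by_region$scenario == sc]),
                 tot$area_thousand_km2[tot$scenario == sc])
  }
  expect_error(landscape_report(list(future = future)), "present")
})

test_that("a collapse scenario shows losses in every region", {
  art <- demo_art()
  g <- art$grids$present
  pres_ens <- art$landscape$network$maps$present
  # synthetic collapse: future suitability is a tenth of present
  ens <- art$network$ensembles$present
  collapsed <- suitability_raster(g, ens$values * 0.1)
  t_use <- art$landscape$network$thresholds$TSS$threshold
  maps <- list(present = binarize(ens, t_use),
               future = binarize(collapsed, t_use))
  rep_tab <- landscape_report(maps, art$regions)
  fut <- rep_tab[rep_tab$scenario == "future" &
                   !is.na(rep_tab$percent_change), ]
  expect_true(all(fut$percent_change < 0))
})
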