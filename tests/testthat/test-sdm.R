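# Grid whose nine cells take bio1 values 1..9 (other variables constant),
# with presences at every cell centre: the envelope trains on exactly 1..9.
envelope_fixture <- function() {
  g <- flat_grid(n_rows = 3, n_cols = 3, cell_size = 0.5)
  g$layers$bio1 <- matrix(1:9, 3, 3)
  g$layers$bio5 <- g$layers$bio1 + 9
  g$layers$bio6 <- g$layers$bio1 - 11
  pres <- expand.grid(col = 1:3, row = 1:3)
  pts <- data.frame(lon = bnsdm:::col_center_lon(g, pres$col),
                    lat = bnsdm:::row_center_lat(g, pres$row))
  list(grid = g, presences = pts)
}

project_at_bio1 <- function(model, values) {
  g <- flat_grid(n_rows = 1, n_cols = length(values), cell_size = 0.5)
  g$layers$bio1 <- matrix(values, 1)
  g$layers$bio5 <- g$layers$bio1 + 9
  g$layers$bio6 <- g$layers$bio1 - 11
  as.vector(project(model, g)$values)
}

test_that("envelope scores follow the mid-rank formula", {
  fx <- envelope_fixture()
  m <- fit_envelope(fx$presences, fx$grid)
  sc <- project_at_bio1(m, c(5, 10, 1, 0.5))
  expect_equal(sc[1], 1.0)            # F = (4 + 0.5)/9 = 0.5 at the median
  expect_equal(sc[2], 0)              # above the training maximum
  expect_equal(sc[3], 2 * 0.5 / 9)    # at the minimum: F = 0.5/9
  expect_equal(sc[4], 0)              # below the training minimum
  expect_error(fit_envelope(fx$presences[1, ], fx$grid), ">= 2")
})

test_that("projection reproduces training scores and respects masks", {
  fx <- envelope_fixture()
  m <- fit_envelope(fx$presences, fx$grid)
  r <- project(m, fx$grid)
  # training-grid projection equals scoring the training cells directly
  expect_equal(extract_suitability(r, fx$presences),
               as.vector(bnsdm:::envelope_score(
                 m, bnsdm:::training_matrix(fx$presences, fx$grid))))
  # a grid fully outside the training range projects to all zeros
  far <- fx$grid
  far$layers$bio1 <- far$layers$bio1 + 100
  far$layers$bio5 <- far$layers$bio1 + 9
  far$layers$bio6 <- far$layers$bio1 - 11
  expect_true(all(project(m, far)$values == 0))
  # masked cells stay masked
  g_na <- fx$grid
  g_na$layers$bio1[1, 1] <- NA
  r_na <- project(m, g_na)
  expect_true(is.na(r_na$values[1, 1]))
  expect_equal(r_na$values[-1], r$values[-1])
})

test_that("logistic fit is bounded and recovers a unimodal niche", {
  g <- gradient_grid(n_rows = 2, n_cols = 100, from = 10, to = 34)
  withr::with_seed(21, {
    cols_p <- sample(which(abs(g$layers$bio1[1, ] - 22) < 3), 60,
                     replace = TRUE)
    cols_b <- sample(100, 120, replace = TRUE)
  })
  pres <- data.frame(lon = bnsdm:::col_center_lon(g, cols_p),
                     lat = bnsdm:::row_center_lat(g, 1))
  bg <- data.frame(lon = bnsdm:::col_center_lon(g, cols_b),
                   lat = bnsdm:::row_center_lat(g, 2))
  m <- fit_logistic(pres, bg, g)
  r <- project(m, g)
  expect_true(all(r$values >= 0 & r$values <= 1))
  # quadratic coefficient on the informative variable must be negative
  expect_lt(m$beta[8], 0)
  # fitted response peaks in the interior, not at the range ends
  prof <- r$values[1, ]
  expect_gt(max(prof), prof[1])
  expect_gt(max(prof), prof[100])
})

test_that("random forest is seeded and separates separable classes", {
  g <- gradient_grid()
  pres <- data.frame(lon = bnsdm:::col_center_lon(g, 1:30),
                     lat = bnsdm:::row_center_lat(g, 1))
  bg <- data.frame(lon = bnsdm:::col_center_lon(g, 71:100),
                   lat = bnsdm:::row_center_lat(g, 2))
  m1 <- fit_forest(pres, bg, g, seed = 5, n_trees = 100)
  m2 <- fit_forest(pres, bg, g, seed = 5, n_trees = 100)
  expect_equal(project(m1, g)$values, project(m2, g)$values)
  r <- project(m1, g)
  expect_true(all(r$values >= 0 & r$values <= 1))
  expect_equal(auc(extract_suitability(r, pres),
                   extract_suitability(r, bg)), 1.0)
})

test_that("rank-based AUC enumerates pairs and handles ties", {
  expect_equal(auc(c(0.9, 0.7), c(0.6, 0.8)), 0.75)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 6)), 0.5)
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  expect_error(auc(numeric(0), 1), "non-empty")
  # invariance under strictly monotone transforms
  set.seed(2)
  p <- runif(25); b <- runif(40)
  expect_equal(auc(p, b), auc(p^3, b^3))
  expect_equal(auc(p, b), auc(plogis(5 * p), plogis(5 * b)))
  # independent route: ROC integration by pROC on scores with ties
  pt <- round(runif(30), 1); bt <- round(runif(50), 1)
  expect_equal(auc(pt, bt),
               as.numeric(pROC::auc(pROC::roc(
                 response = c(rep(1, 30), rep(0, 50)),
                 predictor = c(pt, bt), quiet = TRUE, direction = "<"))))
})

test_that("k-fold cross-validation partitions and summarises correctly", {
  g <- gradient_grid()
  withr::with_seed(8, {
    cols_p <- sample(which(abs(g$layers$bio1[1, ] - 20) < 4), 24,
                     replace = TRUE)
    cols_b <- sample(100, 40, replace = TRUE)
  })
  pres <- data.frame(lon = bnsdm:::col_center_lon(g, cols_p),
                     lat = bnsdm:::row_center_lat(g, 1))
  bg <- data.frame(lon = bnsdm:::col_center_lon(g, cols_b),
                   lat = bnsdm:::row_center_lat(g, 2))
  cv <- kfold_auc(function(p, b, gr) fit_envelope(p, gr), pres, bg, g,
                  k = 4, seed = 3)
  expect_length(cv$fold_auc, 4)
  expect_equal(cv$mean_auc, mean(cv$fold_auc))
  expect_equal(cv$sd_auc, sd(cv$fold_auc))
  cv2 <- kfold_auc(function(p, b, gr) fit_envelope(p, gr), pres, bg, g,
                   k = 4, seed = 3)
  expect_identical(cv$fold_auc, cv2$fold_auc)
  expect_error(kfold_auc(function(p, b, gr) fit_envelope(p, gr),
                         pres[1:3, ], bg, g, k = 4, seed = 1),
               "exceeds")
})

test_that("background sampling avoids presences and is exhaustive at n max", {
  g <- flat_grid(n_rows = 4, n_cols = 5)
  pres <- data.frame(lon = bnsdm:::col_center_lon(g, c(1, 2)),
                     lat = bnsdm:::row_center_lat(g, c(1, 1)))
  bg <- sample_background(g, 18, seed = 1, exclude = pres)
  expect_equal(nrow(bg), 18)
  idx_b <- cell_index(g, bg$lon, bg$lat)
  idx_p <- cell_index(g, pres$lon, pres$lat)
  expect_equal(nrow(merge(idx_b, idx_p)), 0)
  expect_equal(nrow(unique(idx_b)), 18)  # the full non-presence set
  expect_identical(bg, sample_background(g, 18, seed = 1, exclude = pres))
  expect_error(sample_background(g, 19, seed = 1, exclude = pres),
               "available")
})

test_that("ensembling is a weighted mean staying inside the input range", {
  g <- flat_grid(n_rows = 2, n_cols = 2)
  a <- suit_from_matrix(matrix(0.2, 2, 2), g)
  b <- suit_from_matrix(matrix(0.6, 2, 2), g)
  e <- ensemble(list(a, b), c(0.6, 0.8))
  expect_equal(e$values[1, 1], (0.2 * 0.6 + 0.6 * 0.8) / 1.4)
  expect_equal(round(e$values[1, 1], 4), 0.4286)
  expect_equal(ensemble(list(a, b), c(1, 1))$values,
               (a$values + b$values) / 2)
  expect_equal(ensemble(list(a), 2)$values, a$values)
  expect_error(ensemble(list(a, b), c(0, 0)), "weights")
  set.seed(4)
  rs <- lapply(1:3, function(i) suit_from_matrix(matrix(runif(4), 2, 2), g))
  w <- runif(3)
  ev <- ensemble(rs, w)$values
  lo <- pmin(rs[[1]]$values, rs[[2]]$values, rs[[3]]$values)
  hi <- pmax(rs[[1]]$values, rs[[2]]$values, rs[[3]]$values)
  expect_true(all(ev >= lo - 1e-12 & ev <= hi + 1e-12))
})

test_that("envelope training quantiles recover the true niche", {
  # wide uniform climate gradient spanning +/- 4 niche breadths: presence
  # climates are then Gaussian around the optimum and training quantiles
  # estimate the true niche quantiles
  opt <- 22; breadth <- 2.5
  g <- gradient_grid(n_rows = 2, n_cols = 500,
                     from = opt - 4 * breadth, to = opt + 4 * breadth)
  # only bio1 is informative: all other breadths effectively infinite
  sp <- virtual_species(
    "recov",
    niche_optimum = c(bio1 = opt, bio5 = opt + 9, bio6 = opt - 11,
                      bio12 = 450, bio13 = 110, bio14 = 10),
    niche_breadth = c(bio1 = breadth, bio5 = 1e6, bio6 = 1e6,
                      bio12 = 1e6, bio13 = 1e6, bio14 = 1e6),
    max_prob = 1)
  occ <- sample_occurrences(sp, g, 2000, seed = 1)
  m <- fit_envelope(occ, g)
  train <- m$train$bio1
  for (p in c(0.25, 0.5, 0.75)) {
    expect_lt(abs(quantile(train, p) - qnorm(p, opt, breadth)),
              0.05 * breadth)
  }
})
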