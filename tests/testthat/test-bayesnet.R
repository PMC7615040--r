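one_cell <- flat_grid(n_rows = 1, n_cols = 1)
resolve1 <- resolve_scalar

test_that("top-k condensation keeps per-cell order statistics", {
  g <- flat_grid(n_rows = 1, n_cols = 2)
  vals <- c(0.1, 0.9, 0.4, 0.7)
  rs <- lapply(vals, function(v) suit_from_matrix(matrix(c(v, v / 2), 1, 2), g))
  top <- condense_top_k(rs, k = 3)
  expect_equal(vapply(top, function(r) r$values[1, 1], numeric(1)),
               c(0.9, 0.7, 0.4))
  expect_equal(vapply(top, function(r) r$values[1, 2], numeric(1)),
               c(0.45, 0.35, 0.2))
  all4 <- condense_top_k(rs, k = 4)
  expect_equal(vapply(all4, function(r) r$values[1, 1], numeric(1)),
               sort(vals, decreasing = TRUE))
  same <- condense_top_k(rs[c(1, 1, 1)], k = 3)
  expect_true(all(vapply(same, function(r) r$values[1, 1], numeric(1)) == 0.1))
  expect_error(condense_top_k(rs[1:2], k = 3), "at least k")
})

test_that("resolution matches the hand-computed worked examples", {
  or5 <- resolution_config("OR", alpha = 0.5)
  expect_equal(resolve1(0.5, list(), or5), 0.5)  # no parents: identity
  expect_equal(resolve1(0.5, list(list(q = 0.8, sign = "+")), or5),
               0.8 * 0.75 + 0.2 * 0.5)  # = 0.70
  expect_equal(resolve1(0.5, list(list(q = 1.0, sign = "-")), or5), 0.25)
})

test_that("with a single parent per direction OR and AND coincide", {
  for (p in c(0.2, 0.7)) for (q1 in c(0.3, 0.9)) for (q2 in c(0.1, 0.8)) {
    parents <- list(list(q = q1, sign = "+"), list(q = q2, sign = "-"))
    expect_equal(resolve1(p, parents, resolution_config("OR", 0.4)),
                 resolve1(p, parents, resolution_config("AND", 0.4)))
  }
})

test_that("resolve equals the brute-force enumeration oracle", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(0:6, 1)
    parents <- lapply(seq_len(n), function(i) {
      list(q = runif(1), sign = sample(c("+", "-"), 1))
    })
    p <- runif(1)
    cfg <- resolution_config(sample(c("OR", "AND"), 1), runif(1))
    expect_equal(resolve1(p, parents, cfg),
                 enumerate_posterior(p, parents, cfg), tolerance = 1e-13)
  }
  expect_error(enumerate_posterior(0.5, rep(list(list(q = 0.5, sign = "+")),
                                            13)),
               "12 parents")
})

test_that("alpha = 0 leaves the prior untouched and posteriors stay bounded", {
  set.seed(13)
  for (rep in 1:25) {
    parents <- lapply(seq_len(sample(1:5, 1)), function(i) {
      list(q = runif(1), sign = sample(c("+", "-"), 1))
    })
    p <- runif(1)
    expect_equal(resolve1(p, parents, resolution_config("OR", 0)), p)
    for (m in c("OR", "AND")) {
      v <- resolve1(p, parents, resolution_config(m, runif(1)))
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("posterior is monotone in each parent's probability", {
  set.seed(29)
  eps <- 1e-4
  for (rep in 1:40) {
    n <- sample(1:5, 1)
    parents <- lapply(seq_len(n), function(i) {
      list(q = runif(1, 0.05, 0.95), sign = sample(c("+", "-"), 1))
    })
    p <- runif(1)
    cfg <- resolution_config(sample(c("OR", "AND"), 1), runif(1, 0.1, 0.9))
    base <- resolve1(p, parents, cfg)
    j <- sample(n, 1)
    bumped <- parents
    bumped[[j]]$q <- bumped[[j]]$q + eps
    delta <- resolve1(p, bumped, cfg) - base
    if (parents[[j]]$sign == "+") expect_gte(delta, -1e-12)
    else expect_lte(delta, 1e-12)
  }
})

test_that("resolution cost grows linearly, not exponentially, in parents", {
  g <- flat_grid(n_rows = 30, n_cols = 30)
  prior <- suit_from_matrix(matrix(0.5, 30, 30), g)
  parents <- lapply(1:200, function(i) {
    list(raster = suit_from_matrix(matrix(runif(900), 30, 30), g),
         sign = if (i %% 2) "+" else "-")
  })
  elapsed <- system.time(
    post <- resolve(prior, parents, resolution_config("OR", 0.5)))["elapsed"]
  expect_lt(elapsed, 5)  # 2^200 outcomes are closed-formed away
  expect_true(all(post$values >= 0 & post$values <= 1))
})

test_that("network construction rejects malformed step lists", {
  edges <- data.frame(parent = c("a", "b"), child = c("f", "f"),
                      sign = c("+", "-"), subnetwork_order = c(0L, 0L))
  expect_s3_class(interaction_network(edges, "f"), "interaction_network")
  expect_error(interaction_network(transform(edges, sign = c("+", "x")), "f"),
               "sign")
  expect_error(interaction_network(transform(edges, child = c("f", "g")), "f"),
               "focal")
  # a sub-focal consumed before its own resolution step is a cycle
  bad <- data.frame(parent = c("t2", "x", "t"), child = c("t", "t2", "f"),
                    sign = "+", subnetwork_order = c(1L, 2L, 0L))
  expect_error(interaction_network(bad, "f"), "cyclic")
  expect_error(interaction_network(
    data.frame(parent = "f", child = "f", sign = "+",
               subnetwork_order = 0L), "f"))
})

test_that("sub-network chaining substitutes posteriors as priors", {
  or5 <- resolution_config("OR", 0.5)
  edges <- data.frame(parent = c("elephant", "tree"),
                      child = c("tree", "focal"),
                      sign = c("-", "+"),
                      subnetwork_order = c(1L, 0L))
  net <- interaction_network(edges, "focal")
  mk <- function(v) scalar_raster(v, one_cell)
  # elephant certain: tree 0.8 -> 0.4; focal 0.5 with q=0.4 -> 0.60
  post <- resolve_chain(net, list(elephant = mk(1), tree = mk(0.8),
                                  focal = mk(0.5)), or5)
  expect_equal(post$values[1, 1], 0.4 * 0.75 + 0.6 * 0.5)
  # absent elephant: the chain reduces to the direct tree -> focal star
  post0 <- resolve_chain(net, list(elephant = mk(0), tree = mk(0.8),
                                   focal = mk(0.5)), or5)
  direct <- interaction_network(
    data.frame(parent = "tree", child = "focal", sign = "+",
               subnetwork_order = 0L), "focal")
  expect_equal(post0$values,
               resolve_chain(direct, list(tree = mk(0.8), focal = mk(0.5)),
                             or5)$values)
  # an empty sub-network list is just the main star
  expect_equal(resolve_chain(direct, list(tree = mk(0.8), focal = mk(0.5)),
                             or5)$values[1, 1],
               resolve1(0.5, list(list(q = 0.8, sign = "+")), or5))
  expect_error(resolve_chain(net, list(tree = mk(0.8), focal = mk(0.5)), or5),
               "missing prior")
})
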