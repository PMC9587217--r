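# VAR fitting and time-domain conditional Granger causality.

test_that("pooled-block least squares recovers known VAR coefficients", {
  K <- 4
  coeffs <- array(0, c(K, K, 2))
  for (i in 1:K) coeffs[i, i, ] <- c(0.5, -0.2)
  coeffs[1, 2, 1] <- 0.3
  coeffs[3, 4, 2] <- -0.25
  truth <- mm_truth_from_coeffs(coeffs)
  ses <- generate_var_lfp(truth, n_blocks = 20, block_len = 5, seed = 21)
  fit <- fit_var(as_blockset(ses)$blocks, 2)
  rmse <- sqrt(mean((fit$coeffs - coeffs)^2))
  expect_lt(rmse, 0.05)
  expect_equal(fit$residual_cov, diag(K), tolerance = 0.05)

  # white noise: all lag coefficients tiny
  set.seed(4)
  blocks <- lapply(1:5, function(b) matrix(rnorm(4 * 4000), 4))
  fitw <- fit_var(blocks, 3)
  expect_lt(quantile(abs(fitw$coeffs), 0.95), 3 / sqrt(fitw$n_effective))

  expect_error(fit_var(blocks, 0), "order")
})

test_that("AIC order selection finds the generating order", {
  K <- 3
  coeffs <- array(0, c(K, K, 3))
  for (i in 1:K) coeffs[i, i, ] <- c(0.4, -0.3, 0.2)
  truth <- mm_truth_from_coeffs(coeffs)
  ses <- generate_var_lfp(truth, n_blocks = 10, block_len = 5, seed = 8)
  sel <- select_var_order(as_blockset(ses)$blocks, orders = 1:6)
  expect_equal(sel$order, 3)
})

test_that("conditional GC matches the analytic population value", {
  # bivariate coupling embedded among independent channels
  K <- 8
  coeffs <- array(0, c(K, K, 2))
  for (i in 1:K) coeffs[i, i, 1] <- 0.5
  coeffs[1, 2, 1] <- 0.4  # channel 2 -> channel 1
  truth <- mm_truth_from_coeffs(coeffs)
  Fpop <- population_gc(coeffs, diag(K), source = 2, target = 1)
  # independent oracle: Szego/Kolmogorov formula for the univariate reduced
  # variance of the target, computed from the true bivariate sub-spectrum
  nfft <- 4096
  om <- 2 * pi * (0:(nfft - 1)) / nfft
  H2 <- micromod:::mm_var_transfer(coeffs[1:2, 1:2, , drop = FALSE], om)
  S2 <- micromod:::mm_var_spectrum(H2, diag(2))
  s11 <- vapply(seq_len(nfft), function(m) Re(S2[1, 1, m]), numeric(1))
  F_szego <- mean(log(s11))  # log reduced variance (full-model var = 1)
  expect_equal(Fpop, F_szego, tolerance = 1e-6)

  ses <- generate_var_lfp(truth, n_blocks = 20, block_len = 5, seed = 42)
  gcm <- conditional_gc_matrix(as_blockset(ses)$blocks, 2)
  expect_lt(abs(gcm$F[2, 1] - Fpop) / Fpop, 0.05)
  expect_lt(gcm$F[1, 2], 0.005)       # no reverse causality
  expect_true(all(gcm$F >= 0))
  expect_equal(diag(gcm$F), rep(0, K))

  # estimator consistency: error shrinks with more data
  ses_s <- generate_var_lfp(truth, n_blocks = 4, block_len = 5, seed = 43)
  gcm_s <- conditional_gc_matrix(as_blockset(ses_s)$blocks, 2)
  expect_lt(abs(gcm$F[2, 1] - Fpop), abs(gcm_s$F[2, 1] - Fpop) + 0.01)
})

test_that("GC is invariant to channel-wise rescaling", {
  set.seed(9)
  blocks <- lapply(1:4, function(b) matrix(rnorm(5 * 2000), 5))
  g1 <- conditional_gc_matrix(blocks, 2)
  scl <- c(0.1, 2, 5, 0.5, 10)
  blocks2 <- lapply(blocks, function(b) b * scl)
  g2 <- conditional_gc_matrix(blocks2, 2)
  expect_equal(g1$F, g2$F, tolerance = 1e-10)
})

test_that("pairwise-conditional GC suppresses indirect chain links", {
  # z -> y -> x with no direct z -> x: conditional F_{z->x} should not be
  # declared significant (at most alpha of seeds, Monte-Carlo oracle)
  K <- 5
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    coeffs <- array(0, c(K, K, 1))
    for (i in 1:K) coeffs[i, i, 1] <- 0.4
    coeffs[2, 3, 1] <- 0.5  # z(3) -> y(2)
    coeffs[1, 2, 1] <- 0.5  # y(2) -> x(1)
    truth <- mm_truth_from_coeffs(coeffs)
    ses <- generate_var_lfp(truth, n_blocks = 10, block_len = 2,
                            seed = 100 + s)
    gcm <- gc_significance(conditional_gc_matrix(as_blockset(ses)$blocks, 2))
    # direct links detected, indirect not
    expect_true(gcm$mask[3, 2])
    expect_true(gcm$mask[2, 1])
    if (gcm$mask[3, 1]) hits <- hits + 1
  }
  expect_lte(hits / n_seeds, 0.05 + 1e-9)
})

test_that("significance thresholding keeps raw F and zeroes the rest", {
  set.seed(12)
  blocks <- lapply(1:8, function(b) matrix(rnorm(6 * 2500), 6))
  gcm <- conditional_gc_matrix(blocks, 2)
  gs <- gc_significance(gcm, alpha = 0.05)
  expect_true(all(gs$thresholded[!gs$mask] == 0))
  expect_true(all(gs$thresholded[gs$mask] == gs$F[gs$mask]))
  # all-zero F: empty mask
  g0 <- gcm; g0$F[] <- 0
  expect_false(any(gc_significance(g0)$mask))
  # strong planted edge survives correction
  fx <- fixture_two_module()
  gcp <- gc_significance(conditional_gc_matrix(
    as_blockset(fx$sessions[[1]])$blocks, 8))
  e <- fx$truth$edges[fx$truth$edges$type == "within", ][1, ]
  expect_true(gcp$mask[e$source, e$target])
})
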