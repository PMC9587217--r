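# Wilson factorization, conditional spectral GC, and band aggregation.

test_that("Wilson factorization recovers the innovation structure", {
  A <- array(0, c(2, 2, 1))
  A[, , 1] <- rbind(c(0.5, 0.3), c(0.0, 0.7))
  Sig <- diag(c(1, 2))
  nfft <- 512
  om <- 2 * pi * (0:(nfft - 1)) / nfft
  H <- micromod:::mm_var_transfer(A, om)
  S <- micromod:::mm_var_spectrum(H, Sig)
  w <- wilson_factorize(S, maxit = 500, tol = 1e-11)
  expect_equal(w$Sigma, Sig, tolerance = 1e-6)
  # psi psi* reconstructs the spectrum at every frequency
  err <- max(vapply(seq_len(nfft), function(m) {
    ps <- w$psi[, , m]
    max(Mod(ps %*% Conj(t(ps)) - S[, , m]))
  }, numeric(1)))
  expect_lt(err, 1e-6)
})

test_that("spectral GC integrates to the time-domain statistic", {
  truth <- make_dense_var_truth(n_channels = 8, order = 3,
                                strength = c(0.02, 0.06), seed = 31)
  ses <- generate_var_lfp(truth, n_blocks = 20, block_len = 5, seed = 32)
  sgc <- spectral_conditional_gc(as_blockset(ses), order = 6, fs = 1000,
                                 nfreq = 256)
  Fint <- spectral_integral(sgc)
  Ftd <- sgc$time_domain$F
  off <- row(Ftd) != col(Ftd)
  rel <- abs(Fint[off] - Ftd[off]) / pmax(Ftd[off], 1e-12)
  expect_lt(median(rel), 0.02)
  expect_true(all(sgc$f >= 0))
})

test_that("oscillatory coupling peaks in its frequency band", {
  fx <- fixture_two_module()
  sgc <- spectral_conditional_gc(as_blockset(fx$sessions[[1]]), order = 8,
                                 fs = 1000, nfreq = 256)
  e <- fx$truth$edges[fx$truth$edges$type == "within", ][1, ]
  pk <- sgc$freq[which.max(sgc$f[e$source, e$target, ])]
  expect_gte(pk, 70)
  expect_lte(pk, 150)

  # independent channels: flat near-zero spectra
  set.seed(6)
  blocks <- lapply(1:6, function(b) matrix(rnorm(4 * 2500), 4))
  sgc0 <- spectral_conditional_gc(blocks, order = 2, fs = 1000, nfreq = 128)
  expect_lt(max(sgc0$f), 0.01)
})

test_that("band aggregation follows the band-average convention", {
  # flat unit-area spectrum over 0-500 Hz: every band value = 1/500
  sgc <- structure(list(
    f = array(1 / 500, c(2, 2, 257)),
    freq = 1000 * (0:256) / 512, fs = 1000, K = 2,
    n_clipped = 0L, normalized = FALSE), class = "mm_sgc")
  bc <- band_contributions(sgc, normalize = FALSE)
  expect_true(all(abs(bc$values - 1 / 500) < 1e-12))

  # normalized spectra integrate to exactly one per pair
  fx <- fixture_two_module()
  sgc2 <- spectral_conditional_gc(as_blockset(fx$sessions[[1]]), order = 8,
                                  fs = 1000, nfreq = 128)
  bcn <- band_contributions(sgc2, normalize = TRUE)
  e <- fx$truth$edges[1, ]
  y <- sgc2$f[e$source, e$target, ]
  area <- micromod:::mm_trapz(sgc2$freq, y / micromod:::mm_trapz(sgc2$freq, y))
  expect_equal(area, 1, tolerance = 1e-12)

  # band outside grid errors
  expect_error(band_contributions(sgc2, bands = list(hf = c(400, 600))),
               "grid")
})

test_that("within-module gamma share exceeds across-module share", {
  fx <- fixture_two_module()
  sgc <- spectral_conditional_gc(as_blockset(fx$sessions[[1]]), order = 8,
                                 fs = 1000, nfreq = 256)
  bc <- band_contributions(sgc, normalize = TRUE)
  gcm <- gc_significance(sgc$time_domain)
  sig <- gcm$mask[cbind(bc$pairs$source, bc$pairs$target)]
  same <- fx$map$labels[bc$pairs$source] == fx$map$labels[bc$pairs$target]
  wt <- bc$values[same & sig, "gamma"]
  ac <- bc$values[!same & sig, "gamma"]
  expect_gt(length(wt), 3)
  expect_gt(length(ac), 3)
  expect_gt(mean(wt), mean(ac))
  expect_lt(wilcox.test(wt, ac, alternative = "greater")$p.value, 0.05)
  # and the reverse for the low-frequency bands
  expect_lt(mean(bc$values[same & sig, "delta"]),
            mean(bc$values[!same & sig, "delta"]))
})
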