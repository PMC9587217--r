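# LFP cleaning chain: rejection, referencing, detrending, line noise,
# artifact interpolation, and block extraction.

test_that("electrode rejection flags extreme channels and is idempotent", {
  set.seed(2)
  lay <- make_layout(8, 8, 0.4)
  x <- matrix(rnorm(64 * 20000), 64)
  x[17, ] <- x[17, ] * 10  # 100x variance
  ses <- mm_session_from_matrix(x, layout = lay)
  sr <- reject_bad_electrodes(ses)
  expect_equal(sr$rejected_channels, 17)
  expect_equal(nrow(sr$lfp), 63)
  # second pass removes nothing
  sr2 <- reject_bad_electrodes(sr)
  expect_equal(nrow(sr2$lfp), 63)
  # homogeneous channels: none removed
  ses_h <- mm_session_from_matrix(matrix(rnorm(64 * 5000), 64), layout = lay)
  expect_equal(length(reject_bad_electrodes(ses_h)$rejected_channels), 0)
  # all-flagged is impossible by construction, but < 8 channels errors
  expect_error(reject_bad_electrodes(
    mm_session_from_matrix(matrix(rnorm(4 * 100), 4))), "8 channels")
})

test_that("common average reference zeroes the cross-channel mean", {
  set.seed(3)
  x <- matrix(rnorm(8 * 1000), 8)
  ses <- mm_session_from_matrix(x + 5)  # constant offset on all channels
  out <- common_average_reference(mm_session_from_matrix(
    matrix(5, 8, 100)))
  expect_true(all(out$lfp == 0))
  out2 <- common_average_reference(ses)
  expect_lt(max(abs(colMeans(out2$lfp))), 1e-12)
  # unit impulse on one channel: (N-1)/N there, -1/N elsewhere
  xi <- matrix(0, 8, 10); xi[3, 5] <- 1
  o3 <- common_average_reference(mm_session_from_matrix(xi))
  expect_equal(o3$lfp[3, 5], 7 / 8)
  expect_equal(o3$lfp[1, 5], -1 / 8)
  expect_error(common_average_reference(
    structure(list(lfp = matrix(1, 1, 10)), class = "mm_session")))
})

test_that("local detrending removes slow components, keeps fast ones", {
  fs <- 1000; n <- 60 * fs; tt <- (1:n) / fs
  slow <- sin(2 * pi * 0.5 * tt)
  out_slow <- micromod:::mm_local_detrend_vec(slow, 500, 250)
  att <- mm_amp_at(out_slow, 0.5, fs) / mm_amp_at(slow, 0.5, fs)
  expect_lt(20 * log10(att), -10)  # at least 10 dB down
  fast <- sin(2 * pi * 40 * tt)
  out_fast <- micromod:::mm_local_detrend_vec(fast, 500, 250)
  expect_lt(abs(mm_amp_at(out_fast, 40, fs) - 1), 0.05)
  expect_equal(max(abs(micromod:::mm_local_detrend_vec(rep(3, 5000),
                                                       500, 250))), 0)
  ses <- mm_session_from_matrix(matrix(rnorm(8 * 1000), 8))
  expect_error(local_detrend(ses, window = 10), "window")
})

test_that("line-noise regression removes the base tone and harmonics", {
  set.seed(5)
  fs <- 1000; n <- 35 * fs; tt <- (1:n) / fs
  x <- matrix(rnorm(8 * n, sd = 0.1), 8, n, byrow = FALSE)
  tone60 <- 0.05 * sin(2 * pi * 60 * tt)     # 50 uV in mV units
  tone180 <- 0.03 * cos(2 * pi * 180 * tt)
  xl <- sweep(x, 2, -(tone60 + tone180))
  ses <- mm_session_from_matrix(xl)
  out <- remove_line_noise(ses, base = 60)
  expect_equal(ncol(out$lfp), n)
  expect_lt(mm_amp_at(out$lfp[1, ], 60, fs), 0.001)   # < 1 uV residual
  expect_lt(mm_amp_at(out$lfp[1, ], 180, fs), 0.001)
  # broadband noise untouched
  ses_n <- mm_session_from_matrix(x)
  out_n <- remove_line_noise(ses_n, base = 60)
  expect_gt(cor(out_n$lfp[1, ], x[1, ]), 0.999)
  expect_error(remove_line_noise(mm_session_from_matrix(x, fs = 100)))
})

test_that("artifact interpolation flags by scaled MAD and fills smoothly", {
  set.seed(6)
  clip <- pmin(pmax(rnorm(3000), -3.5), 3.5)  # bounded noise, one artifact
  clip[1500] <- 10 * max(abs(clip))
  res <- interpolate_artifacts(clip)
  expect_true(res$usable)
  expect_equal(sum(res$mask), 11)  # +-5 samples around the spike
  expect_true(all(which(res$mask) == 1495:1505))
  # monotone interpolation stays within the neighbors' envelope
  env <- range(clip[c(1490:1494, 1506:1510)])
  expect_true(all(res$x[res$mask] >= env[1] - 1e-9 &
                    res$x[res$mask] <= env[2] + 1e-9))
  # clean Gaussian clip: flagged fraction near 2*Phi(-4) (MC oracle scale)
  set.seed(7)
  big <- rnorm(2e5)
  resg <- interpolate_artifacts(big, pad = 0)
  expect_lt(mean(resg$mask), 6e-4)
  # all-constant clip: MAD = 0 handled as no-op
  resc <- interpolate_artifacts(rep(2, 1500))
  expect_false(any(resc$mask))
  expect_equal(resc$x, rep(2, 1500))
  # majority-flagged clip marked unusable (dense spikes + padding)
  weird <- rnorm(1000)
  weird[seq(1, 1000, by = 8)] <- 50
  expect_false(interpolate_artifacts(weird)$usable)
})

test_that("block extraction avoids artifact-laden windows", {
  set.seed(8)
  fs <- 1000
  x <- matrix(rnorm(4 * 60 * fs), 4)  # two 30-s clips
  # dense artifacts throughout seconds 0-10 of the first clip
  x[2, seq(1, 10 * fs, by = 40)] <- 100
  ses <- mm_session_from_matrix(x)
  bl <- extract_blocks(ses, n_clips = 2, clip_len = 30, block_len = 5)
  expect_equal(length(bl$blocks), 2)
  expect_equal(ncol(bl$blocks[[1]]), 5000)
  expect_gte(bl$block_starts[1], 10 * fs - 45)
  expect_equal(bl$interpolated_fraction[1], 0)
  # artifact-free clip: earliest window wins the tie
  expect_equal(bl$block_starts[2], 30 * fs + 1)
  expect_error(extract_blocks(ses, n_clips = 20), "too short")
})
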