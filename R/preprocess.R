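# LFP cleaning: electrode rejection, common average re-referencing, local
# detrending, regression-based line-noise removal, MAD artifact
# interpolation, and extraction of the per-session analysis blocks.
#
# Fixed pipeline order (see preprocess_session): reject -> reference ->
# detrend -> line noise -> clip/interpolate -> block extraction.

#' Reject electrodes with abnormal amplitude or variance
#'
#' Flags channels whose RMS amplitude or variance exceeds the mean across
#' channels by more than three standard deviations, and removes them before
#' re-referencing. The criterion is applied to the current channel set, so a
#' second pass on the output removes nothing.
#'
#' @param session an `mm_session`.
#' @param n_sd rejection threshold in standard deviations (default 3).
#' @return the session with flagged channels removed; `retained_channels`
#'   records the surviving original indices and `rejected_channels` the
#'   removed ones.
#' @export
reject_bad_electrodes <- function(session, n_sd = 3) {
  stopifnot(inherits(session, "mm_session"))
  x <- session$lfp
  if (nrow(x) < 8) stop("electrode rejection requires at least 8 channels")
  rms <- sqrt(rowMeans(x^2))
  v <- apply(x, 1, var)
  bad <- (rms > mean(rms) + n_sd * sd(rms)) | (v > mean(v) + n_sd * sd(v))
  if (all(bad)) stop("all channels flagged as bad")
  keep <- which(!bad)
  prior <- session$retained_channels
  session$lfp <- x[keep, , drop = FALSE]
  session$retained_channels <- prior[keep]
  session$rejected_channels <- c(session$rejected_channels, prior[bad])
  session
}

#' Common average re-referencing
#'
#' Subtracts the across-channel mean from every sample, removing signal
#' components common to the whole array. After referencing the per-sample
#' mean across retained channels is zero.
#'
#' @param session an `mm_session` (retained channels only).
#' @return the re-referenced session.
#' @export
common_average_reference <- function(session) {
  stopifnot(inherits(session, "mm_session"))
  if (nrow(session$lfp) < 2) stop("reference undefined for a single channel")
  session$lfp <- sweep(session$lfp, 2, colMeans(session$lfp))
  session
}

# Internal: local linear detrend of one channel. Fits a least-squares line
# in windows of `wlen` samples every `step` samples, interpolates the fitted
# values at window centers into a running trend, and subtracts it.
mm_local_detrend_vec <- function(x, wlen, step) {
  n <- length(x)
  starts <- seq(1, max(1, n - wlen + 1), by = step)
  centers <- numeric(length(starts))
  fitted <- numeric(length(starts))
  tt <- seq_len(wlen)
  sx <- sum(tt); sxx <- sum(tt^2)
  denom <- wlen * sxx - sx^2
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:min(n, starts[k] + wlen - 1)]
    m <- length(seg)
    if (m == wlen) {
      sy <- sum(seg); sxy <- sum(tt * seg)
      b <- (wlen * sxy - sx * sy) / denom
      a <- (sy - b * sx) / wlen
      fitted[k] <- a + b * (wlen + 1) / 2
    } else {
      fitted[k] <- mean(seg)
    }
    centers[k] <- starts[k] + (min(n, starts[k] + wlen - 1) - starts[k]) / 2
  }
  trend <- stats::approx(centers, fitted, xout = seq_len(n), rule = 2)$y
  x - trend
}

#' Remove slow fluctuations by local linear detrending
#'
#' Running local linear fit (default 0.5 s windows, 0.25 s step) subtracted
#' from each channel, attenuating components below roughly 2 Hz while
#' leaving the physiological bands intact.
#'
#' @param session an `mm_session`.
#' @param window,step window length and step in seconds.
#' @return the detrended session.
#' @export
local_detrend <- function(session, window = 0.5, step = 0.25) {
  stopifnot(inherits(session, "mm_session"))
  wlen <- round(window * session$fs)
  if (wlen > ncol(session$lfp)) stop("detrend window longer than recording")
  stp <- max(1, round(step * session$fs))
  session$lfp <- t(apply(session$lfp, 1, mm_local_detrend_vec,
                         wlen = wlen, step = stp))
  session
}

#' Remove line noise by sinusoid regression
#'
#' Least-squares regression of a sine and cosine at the line frequency and
#' every harmonic below the Nyquist frequency, fitted per clip (default
#' 30 s) and subtracted. The signal is internally resampled so the sampling
#' rate is an integer multiple of the line frequency (1020 Hz for 60 Hz
#' lines at 1 kHz) and resampled back afterwards.
#'
#' @param session an `mm_session`.
#' @param base line frequency in Hz (default 60).
#' @param clip_len regression clip length in seconds (default 30; clipped to
#'   the recording length).
#' @return the cleaned session.
#' @export
remove_line_noise <- function(session, base = 60, clip_len = 30) {
  stopifnot(inherits(session, "mm_session"))
  fs <- session$fs
  if (fs <= 2 * base) stop("sampling rate must exceed twice the line frequency")
  # resample to an integer multiple of the line frequency (delay-free FFT
  # rational resampling, exactly invertible)
  target <- ceiling(fs / base) * base
  rat <- mm_rational(target / fs)
  up <- rat[1]; down <- rat[2]
  n0 <- ncol(session$lfp)
  x <- session$lfp
  resampled <- up != down
  m <- round(n0 * up / down)
  if (resampled)
    x <- t(apply(x, 1, mm_fft_resample, m = m))
  fs2 <- fs * up / down
  n <- ncol(x)
  harmonics <- seq(base, fs2 / 2 - 1e-9, by = base)
  clip_n <- min(n, round(clip_len * fs2))
  starts <- seq(1, n, by = clip_n)
  for (s0 in starts) {
    idx <- s0:min(n, s0 + clip_n - 1)
    tt <- idx / fs2
    D <- do.call(cbind, lapply(harmonics, function(h)
      cbind(sin(2 * pi * h * tt), cos(2 * pi * h * tt))))
    # per-channel least squares against the shared design
    qrD <- qr(D)
    x[, idx] <- x[, idx] - t(qr.fitted(qrD, t(x[, idx, drop = FALSE])))
  }
  if (resampled) x <- t(apply(x, 1, mm_fft_resample, m = n0))
  session$lfp <- x
  session
}

# Internal: small-denominator rational approximation for resampling ratios.
mm_rational <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("no small rational approximation for resampling ratio")
}

# Internal: FFT-based resampling of x to length m (delay-free and exactly
# invertible for signals band-limited below the smaller Nyquist).
mm_fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  Y <- complex(real = rep(0, m))
  if (m > n) {  # upsample: insert zeros at high frequencies
    Y[1:(half + 1)] <- X[1:(half + 1)]
    Y[(m - (n - half - 1) + 1):m] <- X[(half + 2):n]
    if (n %% 2 == 0) {  # split the Nyquist bin symmetrically
      Y[half + 1] <- X[half + 1] / 2
      Y[m - half + 1] <- X[half + 1] / 2
    }
  } else {      # downsample: truncate high frequencies
    hm <- floor(m / 2)
    Y[1:(hm + 1)] <- X[1:(hm + 1)]
    Y[(hm + 2):m] <- X[(n - (m - hm - 1) + 1):n]
    if (m %% 2 == 0) Y[hm + 1] <- Re(X[hm + 1] + X[n - hm + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Flag and interpolate artifact samples in a clip
#'
#' Samples deviating from the clip median by more than `mad_k` scaled median
#' absolute deviations (scale constant 1.4826) are flagged, extended by
#' `pad` samples on each side, and replaced by shape-preserving piecewise
#' cubic Hermite interpolation (PCHIP) through the surrounding clean
#' samples, which keeps the fill bounded by its neighboring values.
#'
#' @param clip numeric vector (one channel, at least 1 s of data).
#' @param mad_k MAD threshold (default 4).
#' @param pad samples replaced on each side of a flagged point (default 5).
#' @param max_frac if more than this fraction is flagged the clip is marked
#'   unusable (default 0.5).
#' @return list with `x` (interpolated clip), `mask` (logical interpolated
#'   samples), `usable`.
#' @export
interpolate_artifacts <- function(clip, mad_k = 4, pad = 5, max_frac = 0.5) {
  n <- length(clip)
  md <- median(clip)
  s <- mad(clip)  # scaled MAD, constant 1.4826
  if (s == 0) return(list(x = clip, mask = rep(FALSE, n), usable = TRUE))
  flagged <- which(abs(clip - md) > mad_k * s)
  mask <- rep(FALSE, n)
  for (f in flagged) mask[max(1, f - pad):min(n, f + pad)] <- TRUE
  if (mean(mask) > max_frac)
    return(list(x = clip, mask = mask, usable = FALSE))
  if (any(mask)) {
    good <- which(!mask)
    out <- clip
    out[mask] <- pracma::pchip(good, clip[good], which(mask))
  } else out <- clip
  list(x = out, mask = mask, usable = TRUE)
}

#' Extract the analysis blocks from a cleaned session
#'
#' Splits the session into `n_clips` non-overlapping clips (default twenty
#' 30-s clips), interpolates artifacts within each clip channel-wise, and
#' retains from each clip the `block_len`-second window (1-sample stride)
#' containing the fewest interpolated samples, ties broken by the earliest
#' start. Block selection ignores any task events.
#'
#' @param session an `mm_session`.
#' @param n_clips number of clips (default 20).
#' @param clip_len clip length in seconds (default 30).
#' @param block_len block length in seconds (default 5).
#' @param mad_k,pad artifact interpolation settings.
#' @return an `mm_blockset` with `interpolated_fraction` and `block_starts`
#'   (sample index of each block in the original recording).
#' @export
extract_blocks <- function(session, n_clips = 20, clip_len = 30,
                           block_len = 5, mad_k = 4, pad = 5) {
  stopifnot(inherits(session, "mm_session"))
  fs <- session$fs
  need <- n_clips * clip_len * fs
  if (ncol(session$lfp) < need)
    stop(sprintf("recording too short: need %g s (%d clips x %g s), have %g s",
                 n_clips * clip_len, n_clips, clip_len,
                 ncol(session$lfp) / fs))
  clip_n <- round(clip_len * fs)
  blk_n <- round(block_len * fs)
  blocks <- vector("list", n_clips)
  frac <- numeric(n_clips)
  starts_abs <- integer(n_clips)
  for (cix in seq_len(n_clips)) {
    idx <- ((cix - 1) * clip_n + 1):(cix * clip_n)
    clip <- session$lfp[, idx, drop = FALSE]
    masks <- matrix(FALSE, nrow(clip), ncol(clip))
    for (ch in seq_len(nrow(clip))) {
      res <- interpolate_artifacts(clip[ch, ], mad_k = mad_k, pad = pad)
      clip[ch, ] <- res$x
      masks[ch, ] <- res$mask
    }
    bad_any <- colSums(masks)  # interpolated samples per time point
    csum <- c(0, cumsum(bad_any))
    wsum <- csum[(blk_n + 1):length(csum)] - csum[1:(length(csum) - blk_n)]
    best <- which.min(wsum)  # earliest minimum
    blocks[[cix]] <- clip[, best:(best + blk_n - 1), drop = FALSE]
    frac[cix] <- mean(masks[, best:(best + blk_n - 1)])
    starts_abs[cix] <- (cix - 1) * clip_n + best
  }
  structure(list(blocks = blocks, block_len = block_len, n_blocks = n_clips,
                 fs = fs, interpolated_fraction = frac,
                 block_starts = starts_abs),
            class = "mm_blockset")
}

#' Full preprocessing pipeline for one session
#'
#' Applies, in order: electrode rejection, common average referencing, local
#' detrending, line-noise regression, and artifact-aware block extraction.
#'
#' @param session an `mm_session`.
#' @param n_clips,clip_len,block_len block extraction settings.
#' @param line_base line frequency (Hz).
#' @return list with `session` (cleaned) and `blocks` (`mm_blockset`).
#' @export
preprocess_session <- function(session, n_clips = 20, clip_len = 30,
                               block_len = 5, line_base = 60) {
  s <- reject_bad_electrodes(session)
  s <- common_average_reference(s)
  s <- local_detrend(s)
  s <- remove_line_noise(s, base = line_base, clip_len = clip_len)
  blocks <- extract_blocks(s, n_clips = n_clips, clip_len = clip_len,
                           block_len = block_len)
  list(session = s, blocks = blocks)
}
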