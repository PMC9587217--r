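# Synthetic modular VAR sessions: multichannel LFP-like signals with planted
# frequency-specific directed coupling and known ground truth.

# Internal: companion matrix of a VAR coefficient array [K, K, p]
# (target-row convention: x_t = sum_k A[,,k] x_{t-k} + e_t).
mm_companion <- function(coeffs) {
  K <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  top <- matrix(coeffs, K, K * p)
  if (p == 1) return(top)
  rbind(top, cbind(diag(K * (p - 1)), matrix(0, K * (p - 1), K)))
}

#' Spectral radius of a VAR coefficient tensor
#'
#' Largest eigenvalue modulus of the companion matrix; the process is stable
#' (stationary) when this is below 1.
#'
#' @param coeffs coefficient array `[K, K, p]`, entry `[i, j, k]` the weight
#'   of channel `j` at lag `k` in the prediction of channel `i`.
#' @return scalar spectral radius.
#' @export
var_spectral_radius <- function(coeffs) {
  max(Mod(eigen(mm_companion(coeffs), only.values = TRUE)$values))
}

# Internal: damped-oscillator AR kernel at a center frequency, unit L2 norm.
# Gives directed couplings whose GC spectrum peaks near `freq`.
mm_osc_kernel <- function(order, freq, fs, damp = 0.9) {
  t <- seq_len(order)
  k <- damp^t * cos(2 * pi * freq * t / fs)
  k / sqrt(sum(k^2))
}

#' Construct the ground-truth VAR for a planted-module session
#'
#' Builds a stable vector autoregression over the electrodes of a planted
#' module map. Within-module ordered pairs are coupled through a
#' damped-oscillator kernel centered in the gamma range and across-module
#' pairs through a low-frequency kernel, so that within-module directed
#' interactions are gamma-weighted and across-module interactions
#' low-frequency-weighted. Cross-couplings are rescaled (preserving the
#' within:across strength ratio) if needed for stability.
#'
#' @param map an `mm_modulemap` from [plant_modules()].
#' @param order VAR model order (lags). Default 8.
#' @param fs sampling rate in Hz.
#' @param within,across lists with elements `freq` (kernel center, Hz),
#'   `strength` (coupling coefficient scale) and `density` (probability that
#'   an ordered pair of that type is coupled).
#' @param self_coefs own-lag coefficients applied to every channel.
#' @param noise_sd innovation standard deviation (mV), common to channels.
#' @param max_radius stability ceiling for the companion spectral radius.
#' @param seed integer seed for the random coupling pattern.
#' @return an object of class `mm_vartruth`: `coeffs`, `noise_cov`, `order`,
#'   `fs`, `band_profile`, `edges` (data.frame source/target/type),
#'   `spectral_radius`, and the module `map`.
#' @export
make_var_truth <- function(map, order = 8, fs = 1000,
                           within = list(freq = 100, strength = 0.15,
                                         density = 0.35),
                           across = list(freq = 8, strength = 0.05,
                                         density = 0.10),
                           self_coefs = c(0.35, -0.12),
                           noise_sd = 1, max_radius = 0.95, seed = NULL) {
  stopifnot(inherits(map, "mm_modulemap"))
  if (fs < 2 * max(within$freq, across$freq))
    stop("fs must be at least twice the highest kernel center frequency")
  K <- length(map$labels)
  coeffs <- array(0, c(K, K, order))
  for (i in seq_len(K))
    coeffs[i, i, seq_along(self_coefs)] <- self_coefs

  kw <- mm_osc_kernel(order, within$freq, fs)
  ka <- mm_osc_kernel(order, across$freq, fs)

  edges <- mm_with_seed(seed, {
    src <- rep(seq_len(K), each = K)
    tgt <- rep(seq_len(K), times = K)
    off <- src != tgt
    src <- src[off]; tgt <- tgt[off]
    same <- map$labels[src] == map$labels[tgt]
    keep_w <- same & runif(length(src)) < within$density
    keep_a <- !same & runif(length(src)) < across$density
    e <- data.frame(source = c(src[keep_w], src[keep_a]),
                    target = c(tgt[keep_w], tgt[keep_a]),
                    type = rep(c("within", "across"),
                               c(sum(keep_w), sum(keep_a))))
    # a directed ring through each module guarantees that every electrode
    # participates in at least one within-module connection
    for (m in seq_len(map$n_modules)) {
      members <- sample(which(map$labels == m))
      if (length(members) >= 2) {
        ring <- data.frame(source = members,
                           target = c(members[-1], members[1]),
                           type = "within")
        e <- rbind(e, ring)
      }
    }
    e[!duplicated(e[, c("source", "target")]), ]
  })
  for (r in seq_len(nrow(edges))) {
    kern <- if (edges$type[r] == "within") kw else ka
    str <- if (edges$type[r] == "within") within$strength else across$strength
    coeffs[edges$target[r], edges$source[r], ] <- str * kern
  }

  # enforce stability, preserving the within:across ratio
  cross_mask <- array(TRUE, dim(coeffs))
  for (i in seq_len(K)) cross_mask[i, i, ] <- FALSE
  radius <- var_spectral_radius(coeffs)
  scale_applied <- 1
  while (radius >= max_radius) {
    fac <- 0.9
    coeffs[cross_mask] <- coeffs[cross_mask] * fac
    scale_applied <- scale_applied * fac
    radius <- var_spectral_radius(coeffs)
  }

  structure(list(coeffs = coeffs, noise_cov = diag(noise_sd^2, K),
                 order = order, fs = fs,
                 band_profile = list(within = within, across = across),
                 edges = edges, spectral_radius = radius,
                 coupling_scale = scale_applied, map = map),
            class = "mm_vartruth")
}

#' Simulate a session of modular VAR LFP blocks
#'
#' Simulates `n_blocks` independent realizations (blocks) of the ground-truth
#' VAR, each with its own innovations and burn-in, mirroring the blocked
#' design in which twenty 5-second segments per session enter the
#' connectivity analysis.
#'
#' @param truth an `mm_vartruth` from [make_var_truth()].
#' @param n_blocks number of blocks (default 20).
#' @param block_len block duration in seconds (default 5).
#' @param seed integer seed.
#' @param session_id label for the session.
#' @param burnin samples discarded at the start of each block.
#' @return an object of class `mm_session`: `lfp` (channels x samples, blocks
#'   concatenated), `fs`, `layout`, `block_len`, `n_blocks`, `session_id`,
#'   and the generating `truth`.
#' @export
generate_var_lfp <- function(truth, n_blocks = 20, block_len = 5,
                             seed = NULL, session_id = "synthetic",
                             burnin = 500) {
  stopifnot(inherits(truth, "mm_vartruth"))
  radius <- var_spectral_radius(truth$coeffs)
  if (radius >= 1)
    stop(sprintf("unstable VAR (companion spectral radius %.3f >= 1)", radius))
  K <- dim(truth$coeffs)[1]; p <- dim(truth$coeffs)[3]
  L <- round(block_len * truth$fs)
  Aflat <- matrix(truth$coeffs, K, K * p)
  # reorder columns so that lag blocks are contiguous: [lag1 ch1..K, lag2 ...]
  # (matrix() above already yields that ordering: dim [K, K*p] with j + K(k-1))
  cholS <- chol(truth$noise_cov)

  lfp <- mm_with_seed(seed, {
    lag <- matrix(0, K * p, n_blocks)  # row block k*K: lag k, all channels
    out <- array(0, c(K, L, n_blocks))
    total <- burnin + L
    for (t in seq_len(total)) {
      e <- t(cholS) %*% matrix(rnorm(K * n_blocks), K, n_blocks)
      x <- Aflat %*% lag + e
      if (p > 1) lag[(K + 1):(K * p), ] <- lag[1:(K * (p - 1)), ]
      lag[1:K, ] <- x
      if (t > burnin) out[, t - burnin, ] <- x
    }
    matrix(out, K, L * n_blocks)
  })
  structure(list(lfp = lfp, fs = truth$fs, layout = truth$map$layout,
                 block_len = block_len, n_blocks = n_blocks,
                 session_id = session_id, truth = truth,
                 retained_channels = seq_len(K)),
            class = "mm_session")
}

#' @export
print.mm_session <- function(x, ...) {
  cat(sprintf("mm_session '%s': %d channels x %d samples @ %g Hz (%d blocks)\n",
              x$session_id, nrow(x$lfp), ncol(x$lfp), x$fs, x$n_blocks))
  invisible(x)
}

#' Split a session into its analysis blocks
#'
#' @param session an `mm_session`.
#' @return an object of class `mm_blockset`: list of channels x samples
#'   matrices with attributes `fs` and `block_len`.
#' @export
as_blockset <- function(session) {
  stopifnot(inherits(session, "mm_session"))
  L <- round(session$block_len * session$fs)
  blocks <- lapply(seq_len(session$n_blocks), function(b) {
    session$lfp[, ((b - 1) * L + 1):(b * L), drop = FALSE]
  })
  structure(list(blocks = blocks, block_len = session$block_len,
                 n_blocks = session$n_blocks, fs = session$fs,
                 interpolated_fraction = rep(0, session$n_blocks)),
            class = "mm_blockset")
}

#' Generate several sessions from one ground truth
#'
#' Sessions share the planted modules and coupling pattern but have
#' independent innovations, emulating repeated recordings from a stable
#' underlying circuit.
#'
#' @inheritParams generate_var_lfp
#' @param n_sessions number of sessions (typical multi-day recordings yield 3-4).
#' @return list of `mm_session` objects.
#' @export
generate_session_set <- function(truth, n_sessions = 3, n_blocks = 20,
                                 block_len = 5, seed = NULL) {
  lapply(seq_len(n_sessions), function(s) {
    generate_var_lfp(truth, n_blocks = n_blocks, block_len = block_len,
                     seed = mm_child_seed(seed, s),
                     session_id = sprintf("session%02d", s))
  })
}

#' Dense random VAR ground truth for spectral-identity checks
#'
#' A fully-connected random VAR in which every ordered channel pair carries
#' a weak damped-oscillator coupling at a random center frequency. Such
#' systems are well conditioned for the spectral decomposition: every pair's
#' conditional GC is well above the estimation floor while couplings stay
#' weak enough that the two-stage spectral construction integrates to the
#' time-domain statistic accurately.
#'
#' @param n_channels channel count.
#' @param order VAR order.
#' @param fs sampling rate (Hz).
#' @param strength range of per-pair coupling scales (uniform draw).
#' @param freq_range range of kernel center frequencies (Hz).
#' @param self_coefs,noise_sd,max_radius as in [make_var_truth()].
#' @param seed integer seed.
#' @return an `mm_vartruth` (with a trivial single-module map).
#' @export
make_dense_var_truth <- function(n_channels = 16, order = 4, fs = 1000,
                                 strength = c(0.015, 0.05),
                                 freq_range = c(5, 150),
                                 self_coefs = c(0.35, -0.12), noise_sd = 1,
                                 max_radius = 0.95, seed = NULL) {
  K <- n_channels
  side <- ceiling(sqrt(K))
  lay <- make_layout(side, max(2, ceiling(K / side)), 0.4)
  lay$coords <- lay$coords[seq_len(K), , drop = FALSE]
  lay$n <- K
  map <- structure(list(labels = rep(1L, K), n_modules = 1L, layout = lay),
                   class = "mm_modulemap")
  coeffs <- mm_with_seed(seed, {
    cf <- array(0, c(K, K, order))
    for (i in seq_len(K))
      cf[i, i, seq_along(self_coefs)] <- self_coefs
    for (i in seq_len(K)) for (j in seq_len(K)) if (i != j) {
      kern <- mm_osc_kernel(order, runif(1, freq_range[1], freq_range[2]), fs)
      cf[i, j, ] <- runif(1, strength[1], strength[2]) * kern
    }
    cf
  })
  cross_mask <- array(TRUE, dim(coeffs))
  for (i in seq_len(K)) cross_mask[i, i, ] <- FALSE
  radius <- var_spectral_radius(coeffs)
  while (radius >= max_radius) {
    coeffs[cross_mask] <- coeffs[cross_mask] * 0.9
    radius <- var_spectral_radius(coeffs)
  }
  structure(list(coeffs = coeffs, noise_cov = diag(noise_sd^2, K),
                 order = order, fs = fs,
                 band_profile = NULL, edges = NULL,
                 spectral_radius = radius, coupling_scale = 1, map = map),
            class = "mm_vartruth")
}
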