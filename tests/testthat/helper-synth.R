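# Shared fixtures, built once per test run and memoized.

.mm_cache <- new.env(parent = emptyenv())

mm_fixture <- function(name, builder) {
  if (!exists(name, envir = .mm_cache)) assign(name, builder(), envir = .mm_cache)
  get(name, envir = .mm_cache)
}

# A small planted two-module session (16 channels) used across granger /
# mlmod / geometry tests.
fixture_two_module <- function() {
  mm_fixture("two_module", function() {
    lay <- make_layout(4, 4, 0.4)
    map <- suppressWarnings(plant_modules(lay, 2, seed = 1))
    truth <- make_var_truth(map, order = 8, seed = 7)
    sessions <- generate_session_set(truth, n_sessions = 3, n_blocks = 10,
                                     block_len = 5, seed = 9)
    nets <- lapply(sessions, function(s) {
      gcm <- gc_significance(conditional_gc_matrix(as_blockset(s)$blocks, 8))
      functional_network(gcm, lay, s$session_id)
    })
    list(lay = lay, map = map, truth = truth, sessions = sessions,
         nets = nets)
  })
}

# A module-tuned spike session with perfectly shared within-module tuning.
fixture_tuned_spikes <- function() {
  mm_fixture("tuned_spikes", function() {
    lay <- make_layout(2, 4, 0.4)
    map <- suppressWarnings(plant_modules(lay, 2, seed = 1))
    tun <- make_tuning_model(map, n_units = 16, tuning_correlation = 1,
                             seed = 4)
    spk <- generate_spikes(tun, n_trials = 120, seed = 5)
    rates <- suppressWarnings(transform_rates(spk))
    mod_of_unit <- spk$units$module[match(rates$unit_ids,
                                          spk$units$unit_id)]
    list(lay = lay, map = map, tun = tun, spk = spk, rates = rates,
         mod_of_unit = mod_of_unit)
  })
}

# Build an mm_session directly from a channels x samples matrix.
mm_session_from_matrix <- function(x, fs = 1000, layout = NULL,
                                   block_len = 5) {
  if (is.null(layout)) {
    side <- ceiling(sqrt(nrow(x)))
    layout <- make_layout(max(2, side), max(2, ceiling(nrow(x) / side)), 0.4)
  }
  structure(list(lfp = x, fs = fs, layout = layout, block_len = block_len,
                 n_blocks = 1, session_id = "test",
                 retained_channels = seq_len(nrow(x))),
            class = "mm_session")
}

# An mm_vartruth wrapper for hand-built coefficient arrays.
mm_truth_from_coeffs <- function(coeffs, noise_cov = NULL, fs = 1000) {
  K <- dim(coeffs)[1]
  lay <- make_layout(max(2, ceiling(sqrt(K))), max(2, ceiling(sqrt(K))), 0.4)
  lay$coords <- lay$coords[seq_len(K), , drop = FALSE]; lay$n <- K
  map <- structure(list(labels = rep(1L, K), n_modules = 1L, layout = lay),
                   class = "mm_modulemap")
  if (is.null(noise_cov)) noise_cov <- diag(K)
  structure(list(coeffs = coeffs, noise_cov = noise_cov,
                 order = dim(coeffs)[3], fs = fs,
                 spectral_radius = var_spectral_radius(coeffs), map = map),
            class = "mm_vartruth")
}

# FFT amplitude of a pure frequency component.
mm_amp_at <- function(x, f, fs) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(f * n / fs) + 1] / n
}
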