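# Synthetic module-tuned spiking: inhomogeneous Poisson units whose category
# tuning is shared (up to jitter) within planted modules, plus the trial
# table of a four-category image recognition task.

#' Construct a module-tuned spiking model
#'
#' Units are placed on random electrodes and inherit module membership from
#' their electrode. Each module has a preferred stimulus category with gain
#' `pref_gain`; a unit's gain vector is a convex mixture of its module's
#' tuning and a random unit-specific tuning, weighted by
#' `tuning_correlation` (1 = identical tuning within a module).
#'
#' @param map an `mm_modulemap`.
#' @param n_units number of units (default 1.5 per electrode).
#' @param n_categories number of stimulus categories (default 4).
#' @param baseline_rate mean baseline firing rate, spikes/s (default 1.5,
#'   typical of human temporal-lobe units); per-unit rates are log-normal
#'   around this value.
#' @param pref_gain multiplicative response gain for the preferred category
#'   (default 3).
#' @param tuning_correlation within-module tuning sharing in [0, 1]
#'   (default 0.8).
#' @param latency_range module response latency range, s.
#' @param width response kernel SD, s.
#' @param seed integer seed.
#' @return an object of class `mm_tuning`: `units` data.frame (unit_id,
#'   electrode, module, baseline, latency, width), `gains` (units x
#'   categories matrix), and settings.
#' @export
make_tuning_model <- function(map, n_units = NULL, n_categories = 4,
                              baseline_rate = 1.5, pref_gain = 3,
                              tuning_correlation = 0.8,
                              latency_range = c(0.2, 0.4), width = 0.15,
                              seed = NULL) {
  stopifnot(inherits(map, "mm_modulemap"))
  K <- length(map$labels)
  if (is.null(n_units)) n_units <- round(1.5 * K)
  mm_with_seed(seed, {
    electrode <- sample.int(K, n_units, replace = TRUE)
    module <- map$labels[electrode]
    mod_pref <- ((seq_len(map$n_modules) - 1) %% n_categories) + 1
    mod_lat <- runif(map$n_modules, latency_range[1], latency_range[2])
    mod_gain <- matrix(1, map$n_modules, n_categories)
    mod_gain[cbind(seq_len(map$n_modules), mod_pref)] <- pref_gain
    unit_pref <- sample.int(n_categories, n_units, replace = TRUE)
    unit_own <- matrix(1, n_units, n_categories)
    unit_own[cbind(seq_len(n_units), unit_pref)] <- pref_gain
    gains <- tuning_correlation * mod_gain[module, , drop = FALSE] +
      (1 - tuning_correlation) * unit_own
    baseline <- exp(rnorm(n_units, log(baseline_rate), 0.3))
    units <- data.frame(unit_id = seq_len(n_units), electrode = electrode,
                        module = module, baseline = baseline,
                        latency = mod_lat[module] +
                          pmax(-0.05, pmin(0.05, 0.02 * rnorm(n_units))),
                        width = width)
    structure(list(units = units, gains = gains,
                   n_categories = n_categories,
                   tuning_correlation = tuning_correlation,
                   pref_gain = pref_gain, map = map),
              class = "mm_tuning")
  })
}

#' Generate module-tuned Poisson spike trains and a trial table
#'
#' Simulates an image-categorization session: trials are presented in sets
#' of `set_size` images flanked by baseline periods; each unit fires as an
#' inhomogeneous Poisson process with rate
#' `baseline * (1 + (gain_c - 1) * exp(-(t - latency)^2 / (2 width^2)))`
#' around each image onset of category `c`. All trials are marked correct.
#'
#' @param tuning an `mm_tuning` from [make_tuning_model()].
#' @param n_trials total trial count, divisible by the number of categories
#'   (default 240: 60 per category).
#' @param categories category labels.
#' @param trial_spacing onset-to-onset interval, s.
#' @param set_size images per set between baselines (default 60).
#' @param baseline_len baseline duration flanking each set, s (default 2).
#' @param seed integer seed.
#' @return an object of class `mm_spikes`: `spikes` (data.frame unit_id,
#'   spike_time_s), `trials` (trial, onset_s, category, correct),
#'   `baseline` (start_s, end_s), `units`, `tuning`.
#' @export
generate_spikes <- function(tuning, n_trials = 240,
                            categories = c("person", "place", "animal",
                                           "object"),
                            trial_spacing = 1.8, set_size = 60,
                            baseline_len = 2, seed = NULL) {
  stopifnot(inherits(tuning, "mm_tuning"))
  ncat <- length(categories)
  if (ncat != tuning$n_categories)
    stop("category count does not match the tuning model")
  if (n_trials %% ncat != 0) stop("n_trials must be divisible by |categories|")
  if (any(tuning$gains < 0) || any(tuning$units$baseline < 0))
    stop("negative rates are not allowed")

  n_sets <- ceiling(n_trials / set_size)
  onsets <- numeric(n_trials)
  base_periods <- NULL
  t0 <- 0
  tr <- 1
  for (s in seq_len(n_sets)) {
    base_periods <- rbind(base_periods, c(t0, t0 + baseline_len))
    t0 <- t0 + baseline_len
    k <- min(set_size, n_trials - tr + 1)
    onsets[tr:(tr + k - 1)] <- t0 + (seq_len(k) - 1) * trial_spacing
    t0 <- t0 + k * trial_spacing
    tr <- tr + k
  }
  base_periods <- rbind(base_periods, c(t0, t0 + baseline_len))
  t_total <- t0 + baseline_len

  mm_with_seed(seed, {
    cat_idx <- sample(rep(seq_len(ncat), n_trials / ncat))
    trials <- data.frame(trial = seq_len(n_trials), onset_s = onsets,
                         category = categories[cat_idx], correct = TRUE)

    un <- tuning$units
    sp_unit <- integer(0); sp_time <- numeric(0)
    for (u in seq_len(nrow(un))) {
      rb <- un$baseline[u]
      lat <- un$latency[u]; w <- un$width[u]
      times <- runif(rpois(1, rb * t_total), 0, t_total)
      g <- tuning$gains[u, cat_idx]
      # multiplicative response bump per trial
      extra_mean <- rb * pmax(g - 1, 0) * w * sqrt(2 * pi)
      n_extra <- rpois(n_trials, extra_mean)
      if (sum(n_extra) > 0) {
        et <- rep(onsets + lat, n_extra) +
          w * rnorm(sum(n_extra))
        times <- c(times, et[et > 0 & et < t_total])
      }
      # suppression (gain < 1): thin baseline spikes near those onsets
      sup <- which(g < 1)
      if (length(sup) > 0) {
        keep <- rep(TRUE, length(times))
        for (trix in sup) {
          rel <- times - onsets[trix] - lat
          inwin <- abs(rel) < 4 * w
          if (any(inwin)) {
            pdrop <- (1 - g[trix]) * exp(-rel[inwin]^2 / (2 * w^2))
            keep[inwin] <- keep[inwin] & (runif(sum(inwin)) > pdrop)
          }
        }
        times <- times[keep]
      }
      sp_unit <- c(sp_unit, rep(un$unit_id[u], length(times)))
      sp_time <- c(sp_time, times)
    }
    ord <- order(sp_time)
    spikes <- data.frame(unit_id = sp_unit[ord], spike_time_s = sp_time[ord])
    structure(list(spikes = spikes, trials = trials,
                   baseline = data.frame(start_s = base_periods[, 1],
                                         end_s = base_periods[, 2]),
                   units = un, tuning = tuning),
              class = "mm_spikes")
  })
}

#' @export
print.mm_spikes <- function(x, ...) {
  cat(sprintf("mm_spikes: %d units, %d spikes, %d trials (%d categories)\n",
              nrow(x$units), nrow(x$spikes), nrow(x$trials),
              length(unique(x$trials$category))))
  invisible(x)
}
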