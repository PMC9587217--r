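# Rate transformation and population decoding with shuffle controls.

test_that("rate transform z-scores against the baseline statistics", {
  fx <- fixture_tuned_spikes()
  r <- fx$rates
  expect_equal(dim(r$z)[1], 120)
  expect_equal(dim(r$z)[3], length(seq(-0.2, 1.2, by = 0.02)))
  # an untuned unit's task-period rates have ~baseline statistics
  tun0 <- make_tuning_model(fx$map, n_units = 6, pref_gain = 1, seed = 9)
  spk0 <- generate_spikes(tun0, n_trials = 80, seed = 10)
  r0 <- suppressWarnings(transform_rates(spk0))
  # pooled over units (per-unit baseline statistics are noisy by design)
  expect_lt(abs(mean(r0$z)), 0.2)
  unit_sds <- apply(r0$z, 2, sd)
  expect_lt(abs(mean(unit_sds) - 1), 0.3)
})

test_that("silent units are dropped with a warning", {
  fx <- fixture_tuned_spikes()
  spk <- fx$spk
  # add a unit that is silent throughout the baseline periods
  spk$units <- rbind(spk$units,
                     data.frame(unit_id = 999, electrode = 1, module = 1,
                                baseline = 0, latency = 0.2, width = 0.15))
  spk$spikes <- rbind(spk$spikes,
                      data.frame(unit_id = 999,
                                 spike_time_s = spk$trials$onset_s[3] + 0.3))
  expect_warning(r <- transform_rates(spk), "zero baseline")
  expect_false(999 %in% r$unit_ids)
  expect_true(999 %in% r$dropped_units)
})

test_that("untuned population decodes at chance (no information leak)", {
  lay <- make_layout(2, 4, 0.4)
  map <- suppressWarnings(plant_modules(lay, 2, seed = 1))
  tun <- make_tuning_model(map, n_units = 8, pref_gain = 1, seed = 21)
  spk <- generate_spikes(tun, n_trials = 80, seed = 22)
  rates <- suppressWarnings(transform_rates(spk))
  clf <- train_module_classifier(rates, rates$unit_ids, n_early_draws = 3,
                                 max_iter = 150, seed = 23)
  # binomial CI around 0.25 at n = 80 hold-out predictions
  expect_lt(abs(clf$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / 80))
})

test_that("tuned module decodes above chance with significant shuffle test", {
  fx <- fixture_tuned_spikes()
  uids <- fx$rates$unit_ids[fx$mod_of_unit == 1]
  clf <- train_module_classifier(fx$rates, uids, n_early_draws = 5,
                                 seed = 31)
  expect_gt(clf$accuracy, 0.3)
  sig <- trial_shuffle_significance(clf, fx$rates, seed = 32)
  expect_lt(sig$p, 0.05)
  expect_lt(abs(sig$surrogate_accuracy - 0.25), 0.12)
  expect_error(train_module_classifier(fx$rates, uids[1]), "2 units")
})

test_that("duplicated-unit features leave accuracy unchanged", {
  fx <- fixture_tuned_spikes()
  uids <- fx$rates$unit_ids[fx$mod_of_unit == 1][1:2]
  clf <- train_module_classifier(fx$rates, uids, n_early_draws = 3,
                                 seed = 41)
  # duplicate the feature block by listing the same units twice
  rates2 <- fx$rates
  nz <- dim(rates2$z)
  z2 <- array(0, c(nz[1], nz[2] + 2, nz[3]))
  z2[, seq_len(nz[2]), ] <- rates2$z
  idx <- match(uids, rates2$unit_ids)
  z2[, nz[2] + 1:2, ] <- rates2$z[, idx, ]
  rates2$z <- z2
  rates2$counts <- array(0, dim(z2))
  rates2$unit_ids <- c(rates2$unit_ids, 9001, 9002)
  clf2 <- train_module_classifier(rates2, c(uids, 9001, 9002),
                                  n_early_draws = 3, seed = 41)
  expect_lt(abs(clf2$accuracy - clf$accuracy), 0.08)
})

test_that("shuffle-within preserves accuracy for identically tuned units", {
  fx <- fixture_tuned_spikes()  # tuning_correlation = 1
  uids <- fx$rates$unit_ids[fx$mod_of_unit == 1]
  clf <- train_module_classifier(fx$rates, uids, n_early_draws = 5,
                                 seed = 51)
  sw <- shuffle_within_accuracy(clf, fx$rates, n_iter = 20, seed = 52)
  expect_gt(sw$accuracy, 0.25 + 0.05)           # stays above chance
  expect_lt(abs(sw$accuracy - clf$accuracy), 0.15)
  # reproducibility at n_iter = 1
  s1 <- shuffle_within_accuracy(clf, fx$rates, n_iter = 1, seed = 53)
  s2 <- shuffle_within_accuracy(clf, fx$rates, n_iter = 1, seed = 53)
  expect_identical(s1$fold_accuracy, s2$fold_accuracy)
})

test_that("shuffle-across with the module itself reduces to shuffle-within", {
  fx <- fixture_tuned_spikes()
  uids <- fx$rates$unit_ids[fx$mod_of_unit == 1]
  clf <- train_module_classifier(fx$rates, uids, n_early_draws = 3,
                                 seed = 61)
  sw <- shuffle_within_accuracy(clf, fx$rates, n_iter = 30, seed = 62)
  sa_self <- shuffle_across_accuracy(clf, fx$rates, uids, n_iter = 30,
                                     seed = 62)
  expect_lt(abs(sw$accuracy - sa_self$accuracy), 0.1)
  # across a differently tuned module accuracy collapses toward chance
  uids2 <- fx$rates$unit_ids[fx$mod_of_unit == 2]
  sa <- shuffle_across_accuracy(clf, fx$rates, uids2, n_iter = 30,
                                seed = 63)
  expect_gt(sw$accuracy - sa$accuracy, 0.05)
})

test_that("boundary response similarity separates shared from foreign tuning", {
  fx <- fixture_tuned_spikes()
  bp <- boundary_pairs(fx$map$labels, fx$lay)
  sim <- boundary_response_similarity(fx$rates, bp, min_trial_frac = 0.2)
  ok <- !is.na(sim$per_module$within_mean) &
    !is.na(sim$per_module$across_mean)
  expect_gt(sum(ok), 0)
  expect_gt(sim$pooled_within, sim$pooled_across)
})
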