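# Population decoding of stimulus category from module spiking: baseline
# z-scored square-root rates, cross-validated softmax regression with early
# stopping, trial-shuffle significance, and the shuffle-within /
# shuffle-across module contrast.

#' Transform spike trains into baseline-normalized rate features
#'
#' Counts spikes in a sliding boxcar (default 200 ms window, 20 ms steps,
#' bin centers from -0.2 s to 1.2 s relative to image onset), square-root
#' transforms the counts, and z-scores each unit using the mean and SD of
#' square-root counts in the task's baseline periods. Units with zero
#' baseline SD are dropped with a warning.
#'
#' @param spk an `mm_spikes` (or a spikes data.frame if `trials` and
#'   `baseline` are given).
#' @param trials,baseline trial table and baseline periods (taken from `spk`
#'   when it is an `mm_spikes`).
#' @param bin_width,step boxcar width and step, s.
#' @param window bin-center range relative to onset, s.
#' @return an object of class `mm_rates`: `z` (trials x units x bins),
#'   `counts` (raw spike counts, same shape), `bin_centers`, `unit_ids`,
#'   `trials`, `dropped_units`, `units` (metadata if available).
#' @export
transform_rates <- function(spk, trials = NULL, baseline = NULL,
                            bin_width = 0.2, step = 0.02,
                            window = c(-0.2, 1.2)) {
  if (inherits(spk, "mm_spikes")) {
    trials <- spk$trials
    baseline <- spk$baseline
    units_meta <- spk$units
    spikes <- spk$spikes
  } else {
    spikes <- spk
    units_meta <- NULL
  }
  stopifnot(!is.null(trials), !is.null(baseline))
  if (is.unsorted(trials$onset_s, strictly = TRUE))
    stop("trial onsets must be strictly increasing")

  unit_ids <- sort(unique(spikes$unit_id))
  centers <- seq(window[1], window[2], by = step)
  nb <- length(centers)
  nt <- nrow(trials)
  nu <- length(unit_ids)
  half <- bin_width / 2

  counts <- array(0L, c(nt, nu, nb))
  base_mean <- base_sd <- numeric(nu)
  for (ui in seq_len(nu)) {
    st <- sort(spikes$spike_time_s[spikes$unit_id == unit_ids[ui]])
    for (tr in seq_len(nt)) {
      lo <- trials$onset_s[tr] + centers - half
      counts[tr, ui, ] <- findInterval(lo + bin_width, st) -
        findInterval(lo, st)
    }
    # baseline: non-overlapping bins tiled across the baseline periods
    bc <- integer(0)
    for (b in seq_len(nrow(baseline))) {
      edges <- seq(baseline$start_s[b], baseline$end_s[b], by = bin_width)
      if (length(edges) > 1)
        bc <- c(bc, findInterval(edges[-1], st) -
                  findInterval(edges[-length(edges)], st))
    }
    base_mean[ui] <- mean(sqrt(bc))
    base_sd[ui] <- sd(sqrt(bc))
  }
  drop <- which(is.na(base_sd) | base_sd == 0)
  if (length(drop) > 0) {
    warning(sprintf("dropping %d unit(s) with zero baseline variability",
                    length(drop)))
    keep <- setdiff(seq_len(nu), drop)
  } else keep <- seq_len(nu)
  z <- sqrt(counts[, keep, , drop = FALSE])
  z <- sweep(z, 2, base_mean[keep])
  z <- sweep(z, 2, base_sd[keep], "/")
  structure(list(z = z, counts = counts[, keep, , drop = FALSE],
                 bin_centers = centers, unit_ids = unit_ids[keep],
                 trials = trials, dropped_units = unit_ids[drop],
                 units = units_meta, bin_width = bin_width),
            class = "mm_rates")
}

# ---- softmax regression with early stopping ----

mm_softmax_loss <- function(P, Yix) {
  -mean(log(pmax(P[cbind(seq_along(Yix), Yix)], 1e-12)))
}

mm_softmax_prob <- function(X1, W) {
  eta <- X1 %*% W
  eta <- eta - apply(eta, 1, max)
  E <- exp(eta)
  E / rowSums(E)
}

# Gradient training of multinomial logistic regression, monitored by an
# early-stopping validation set; returns the weights with the best
# validation loss. X, Xval are standardized feature matrices (no intercept
# column); y, yval integer class labels.
mm_softmax_train <- function(X, y, Xval, yval, n_classes, lr = 0.5,
                             max_iter = 300, patience = 10) {
  n <- nrow(X); d <- ncol(X)
  X1 <- cbind(1, X)
  Xv1 <- cbind(1, Xval)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y)] <- 1
  W <- matrix(0, d + 1, n_classes)
  best_W <- W
  best_loss <- Inf
  stall <- 0
  for (it in seq_len(max_iter)) {
    P <- mm_softmax_prob(X1, W)
    grad <- crossprod(X1, P - Y) / n
    W <- W - lr * grad
    vloss <- mm_softmax_loss(mm_softmax_prob(Xv1, W), yval)
    if (vloss < best_loss - 1e-9) {
      best_loss <- vloss
      best_W <- W
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  best_W
}

# Map standardized-space weights back to raw feature space so weights can be
# averaged across early-stopping draws with different z-scoring parameters.
mm_weights_to_raw <- function(W, mu, sdv) {
  Wraw <- W
  Wraw[-1, ] <- W[-1, ] / sdv
  Wraw[1, ] <- W[1, ] - colSums(W[-1, , drop = FALSE] * (mu / sdv))
  Wraw
}

# Internal: feature matrix for a unit subset and bin index set.
# Feature order is unit-major: unit u's bins occupy a contiguous block.
mm_feature_matrix <- function(rates, trial_idx, unit_idx, bin_idx) {
  nt <- length(trial_idx); nu <- length(unit_idx); nb <- length(bin_idx)
  X <- matrix(0, nt, nu * nb)
  for (u in seq_len(nu))
    X[, ((u - 1) * nb + 1):(u * nb)] <-
      rates$z[trial_idx, unit_idx[u], bin_idx]
  X
}

#' Cross-validated category classifier for one module
#'
#' Twenty-fold cross-validated multinomial logistic regression with early
#' stopping, following the population-decoding design: hold-out folds are
#' spread uniformly across the session (about 5% of trials each); within
#' each fold, a quarter of the training trials forms the early-stopping set,
#' redrawn `n_early_draws` times with the fold weights averaged over draws;
#' feature z-scoring parameters come from the remaining training trials
#' only. Only correct trials are used. In `overall` mode features are every
#' third time bin from 0.1 s onward (18 bins per unit); in `per_bin` mode a
#' separate classifier per time bin yields the accuracy time course.
#'
#' @param rates an `mm_rates`.
#' @param unit_ids units (module members) to decode from; at least 2.
#' @param mode `"overall"` or `"per_bin"`.
#' @param n_folds cross-validation folds (default 20).
#' @param n_early_draws early-stopping redraws per fold (default 50).
#' @param lr,max_iter,patience gradient-training controls.
#' @param seed integer seed.
#' @return an object of class `mm_classifier`: `accuracy` (overall mean),
#'   `fold_accuracy`, per-fold raw-space `weights`, fold `test_trials`,
#'   feature metadata, and for `per_bin` mode `bin_accuracy`.
#' @export
train_module_classifier <- function(rates, unit_ids, mode = "overall",
                                    n_folds = 20, n_early_draws = 50,
                                    lr = 0.5, max_iter = 300, patience = 10,
                                    seed = NULL) {
  stopifnot(inherits(rates, "mm_rates"))
  unit_idx <- match(unit_ids, rates$unit_ids)
  if (any(is.na(unit_idx))) stop("unknown unit ids")
  if (length(unit_idx) < 2) stop("decoding requires at least 2 units")
  ok <- which(rates$trials$correct)
  if (length(ok) < n_folds) stop("need at least n_folds correct trials")
  y_all <- as.integer(factor(rates$trials$category[ok]))
  n_classes <- max(y_all)

  if (mode == "overall") {
    targets <- seq(0.1, by = 0.06, length.out = 18)
    bin_idx <- vapply(targets, function(t0)
      which.min(abs(rates$bin_centers - t0)), 0L)
  } else if (mode == "per_bin") {
    bin_idx <- seq_along(rates$bin_centers)
  } else stop("mode must be 'overall' or 'per_bin'")

  run_cv <- function(bins, sd_base) {
    fold_of <- ((seq_along(ok) - 1) %% n_folds) + 1
    Xall <- mm_feature_matrix(rates, ok, unit_idx, bins)
    acc <- numeric(n_folds)
    weights <- vector("list", n_folds)
    tests <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      test <- which(fold_of == f)
      train <- setdiff(seq_along(ok), test)
      Wsum <- NULL
      for (dr in seq_len(n_early_draws)) {
        dseed <- mm_child_seed(sd_base, f * 1000 + dr)
        split <- mm_with_seed(dseed, {
          repeat {
            es <- sample(train, max(1, round(length(train) / 4)))
            rest <- setdiff(train, es)
            if (length(unique(y_all[rest])) == n_classes) break
          }
          list(es = es, rest = rest)
        })
        mu <- colMeans(Xall[split$rest, , drop = FALSE])
        sdv <- apply(Xall[split$rest, , drop = FALSE], 2, sd)
        sdv[sdv == 0 | is.na(sdv)] <- 1
        Xs <- sweep(sweep(Xall[split$rest, , drop = FALSE], 2, mu), 2,
                    sdv, "/")
        Xe <- sweep(sweep(Xall[split$es, , drop = FALSE], 2, mu), 2,
                    sdv, "/")
        W <- mm_softmax_train(Xs, y_all[split$rest], Xe, y_all[split$es],
                              n_classes, lr = lr, max_iter = max_iter,
                              patience = patience)
        Wraw <- mm_weights_to_raw(W, mu, sdv)
        Wsum <- if (is.null(Wsum)) Wraw else Wsum + Wraw
      }
      Wf <- Wsum / n_early_draws
      P <- mm_softmax_prob(cbind(1, Xall[test, , drop = FALSE]), Wf)
      pred <- max.col(P)
      acc[f] <- mean(pred == y_all[test])
      weights[[f]] <- Wf
      tests[[f]] <- test
    }
    list(acc = acc, weights = weights, tests = tests)
  }

  if (mode == "overall") {
    cv <- run_cv(bin_idx, seed)
    structure(list(accuracy = mean(cv$acc), fold_accuracy = cv$acc,
                   weights = cv$weights, test_trials = cv$tests,
                   trial_index = ok, y = y_all, n_classes = n_classes,
                   unit_ids = rates$unit_ids[unit_idx], bin_idx = bin_idx,
                   mode = mode, n_folds = n_folds,
                   n_early_draws = n_early_draws,
                   settings = list(lr = lr, max_iter = max_iter,
                                   patience = patience, seed = seed)),
              class = "mm_classifier")
  } else {
    bin_acc <- vapply(seq_along(bin_idx), function(b) {
      mean(run_cv(bin_idx[b], mm_child_seed(seed, b))$acc)
    }, numeric(1))
    structure(list(bin_accuracy = bin_acc,
                   bin_centers = rates$bin_centers,
                   accuracy = max(bin_acc), mode = mode,
                   unit_ids = rates$unit_ids[unit_idx]),
              class = "mm_classifier")
  }
}

#' @export
print.mm_classifier <- function(x, ...) {
  cat(sprintf("mm_classifier (%s): %d units, accuracy %.3f\n",
              x$mode, length(x$unit_ids), x$accuracy))
  invisible(x)
}

#' Trial-shuffle significance of classification accuracy
#'
#' Refits the classifier with identical machinery but with the category
#' labels of the training and early-stopping trials randomly shuffled
#' (hold-out labels intact), then compares the real and surrogate per-fold
#' accuracies with a paired two-tailed t-test.
#'
#' @param result an `mm_classifier` (overall mode).
#' @param rates the `mm_rates` used to train it.
#' @param seed integer seed for the label shuffle.
#' @return list with `p` (paired t-test p-value), `surrogate_accuracy`,
#'   `surrogate_fold_accuracy`, and `real_fold_accuracy`.
#' @export
trial_shuffle_significance <- function(result, rates, seed = NULL) {
  stopifnot(inherits(result, "mm_classifier"), result$mode == "overall")
  unit_idx <- match(result$unit_ids, rates$unit_ids)
  ok <- result$trial_index
  y_true <- result$y
  y_shuf <- mm_with_seed(seed, sample(y_true))
  Xall <- mm_feature_matrix(rates, ok, unit_idx, result$bin_idx)
  n_folds <- result$n_folds
  fold_of <- ((seq_along(ok) - 1) %% n_folds) + 1
  st <- result$settings
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(fold_of == f)
    train <- setdiff(seq_along(ok), test)
    Wsum <- NULL
    for (dr in seq_len(result$n_early_draws)) {
      dseed <- mm_child_seed(st$seed, f * 1000 + dr)
      split <- mm_with_seed(dseed, {
        repeat {
          es <- sample(train, max(1, round(length(train) / 4)))
          rest <- setdiff(train, es)
          if (length(unique(y_shuf[rest])) == result$n_classes) break
        }
        list(es = es, rest = rest)
      })
      mu <- colMeans(Xall[split$rest, , drop = FALSE])
      sdv <- apply(Xall[split$rest, , drop = FALSE], 2, sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      Xs <- sweep(sweep(Xall[split$rest, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xe <- sweep(sweep(Xall[split$es, , drop = FALSE], 2, mu), 2, sdv, "/")
      W <- mm_softmax_train(Xs, y_shuf[split$rest], Xe, y_shuf[split$es],
                            result$n_classes, lr = st$lr,
                            max_iter = st$max_iter, patience = st$patience)
      Wraw <- mm_weights_to_raw(W, mu, sdv)
      Wsum <- if (is.null(Wsum)) Wraw else Wsum + Wraw
    }
    Wf <- Wsum / result$n_early_draws
    P <- mm_softmax_prob(cbind(1, Xall[test, , drop = FALSE]), Wf)
    acc[f] <- mean(max.col(P) == y_true[test])
  }
  tt <- t.test(result$fold_accuracy, acc, paired = TRUE)
  list(p = tt$p.value, surrogate_accuracy = mean(acc),
       surrogate_fold_accuracy = acc,
       real_fold_accuracy = result$fold_accuracy)
}

# Internal: accuracy of stored fold classifiers on hold-out features with a
# unit-to-slot assignment `slot_units` (vector of unit indices into
# rates$unit_ids, one per classifier slot).
mm_holdout_accuracy <- function(result, rates, slot_units) {
  nb <- length(result$bin_idx)
  acc <- numeric(result$n_folds)
  for (f in seq_len(result$n_folds)) {
    test_local <- result$test_trials[[f]]
    trial_idx <- result$trial_index[test_local]
    X <- mm_feature_matrix(rates, trial_idx, slot_units, result$bin_idx)
    P <- mm_softmax_prob(cbind(1, X), result$weights[[f]])
    acc[f] <- mean(max.col(P) == result$y[test_local])
  }
  acc
}

#' Hold-out accuracy after shuffling unit identities within a module
#'
#' Applies the stored fold classifiers to hold-out data in which the unit
#' identities are randomly permuted among the module's own units, so each
#' unit's weights act on a different unit from the same module. Accuracy is
#' averaged within folds over `n_iter` permutations.
#'
#' @param result an `mm_classifier` (overall mode).
#' @param rates the `mm_rates`.
#' @param n_iter permutations (default 100).
#' @param seed integer seed.
#' @return list with `accuracy` (mean over folds), `fold_accuracy`.
#' @export
shuffle_within_accuracy <- function(result, rates, n_iter = 100,
                                    seed = NULL) {
  stopifnot(inherits(result, "mm_classifier"), result$mode == "overall")
  unit_idx <- match(result$unit_ids, rates$unit_ids)
  nu <- length(unit_idx)
  if (nu == 1) message("single-unit module: permutation is the identity")
  fold_sum <- numeric(result$n_folds)
  for (it in seq_len(n_iter)) {
    perm <- mm_with_seed(mm_child_seed(seed, it), sample.int(nu))
    fold_sum <- fold_sum + mm_holdout_accuracy(result, rates,
                                               unit_idx[perm])
  }
  fa <- fold_sum / n_iter
  list(accuracy = mean(fa), fold_accuracy = fa)
}

#' Hold-out accuracy with units substituted from another module
#'
#' Applies the stored fold classifiers to hold-out data whose features come
#' from a different module's units: when the donor module has at least as
#' many units, a subsample (without replacement) fills the classifier's unit
#' slots; when it has fewer, units are resampled with replacement. A fresh
#' draw is made on each of `n_iter` iterations.
#'
#' @param result an `mm_classifier` trained on module A (overall mode).
#' @param rates the `mm_rates`.
#' @param donor_unit_ids unit ids of module B.
#' @param n_iter iterations (default 100).
#' @param seed integer seed.
#' @return list with `accuracy`, `fold_accuracy`.
#' @export
shuffle_across_accuracy <- function(result, rates, donor_unit_ids,
                                    n_iter = 100, seed = NULL) {
  stopifnot(inherits(result, "mm_classifier"), result$mode == "overall")
  donor_idx <- match(donor_unit_ids, rates$unit_ids)
  if (any(is.na(donor_idx))) stop("unknown donor unit ids")
  na <- length(result$unit_ids)
  nb <- length(donor_idx)
  fold_sum <- numeric(result$n_folds)
  for (it in seq_len(n_iter)) {
    slots <- mm_with_seed(mm_child_seed(seed, it), {
      if (nb >= na) sample(donor_idx, na)
      else sample(donor_idx, na, replace = TRUE)
    })
    fold_sum <- fold_sum + mm_holdout_accuracy(result, rates, slots)
  }
  fa <- fold_sum / n_iter
  list(accuracy = mean(fa), fold_accuracy = fa)
}

#' Response similarity across module boundaries
#'
#' For unit pairs on distance-matched boundary electrode pairs, computes the
#' trial-wise Pearson correlation between the two units' binned response
#' time courses (bin centers 0 to 1.2 s), averaged across trials. Only units
#' that spiked in at least `min_trial_frac` of trials are used. Returns
#' per-module mean similarity for boundary-inside (within) versus
#' boundary-outside (across) pairs.
#'
#' @param rates an `mm_rates` carrying unit metadata (electrode mapping).
#' @param pairs an `mm_boundary` from [boundary_pairs()].
#' @param min_trial_frac minimum fraction of trials with at least one spike
#'   (default 0.5).
#' @return list with `per_module` data.frame (module, within_mean,
#'   across_mean, n_within_pairs, n_across_pairs) and pooled values; modules
#'   with no qualifying pairs are excluded (logged via message).
#' @export
boundary_response_similarity <- function(rates, pairs,
                                         min_trial_frac = 0.5) {
  stopifnot(inherits(rates, "mm_rates"), inherits(pairs, "mm_boundary"))
  if (is.null(rates$units)) stop("rates lack unit-to-electrode metadata")
  resp_bins <- which(rates$bin_centers >= 0 & rates$bin_centers <= 1.2)
  nt <- dim(rates$z)[1]
  spiked <- apply(rates$counts, c(1, 2), sum) > 0  # trial x unit
  qualify <- colMeans(spiked) >= min_trial_frac
  eu <- rates$units[match(rates$unit_ids, rates$units$unit_id), ]

  pair_sim <- function(epairs) {
    sims <- numeric(0)
    if (nrow(epairs) == 0) return(sims)
    for (r in seq_len(nrow(epairs))) {
      u1 <- which(eu$electrode == epairs[r, 1] & qualify)
      u2 <- which(eu$electrode == epairs[r, 2] & qualify)
      for (a in u1) for (b in u2) {
        cors <- vapply(seq_len(nt), function(tr) {
          x <- rates$z[tr, a, resp_bins]
          y <- rates$z[tr, b, resp_bins]
          if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
        }, numeric(1))
        sims <- c(sims, mean(cors, na.rm = TRUE))
      }
    }
    sims
  }

  per <- lapply(names(pairs$pairs), function(m) {
    wi <- pair_sim(pairs$pairs[[m]]$inside)
    ac <- pair_sim(pairs$pairs[[m]]$outside)
    data.frame(module = m,
               within_mean = if (length(wi)) mean(wi) else NA_real_,
               across_mean = if (length(ac)) mean(ac) else NA_real_,
               n_within_pairs = length(wi), n_across_pairs = length(ac))
  })
  per <- do.call(rbind, per)
  ok <- stats::complete.cases(per[, c("within_mean", "across_mean")])
  if (any(!ok))
    message(sprintf("%d module(s) excluded (no qualifying unit pairs)",
                    sum(!ok)))
  list(per_module = per,
       pooled_within = mean(per$within_mean[ok]),
       pooled_across = mean(per$across_mean[ok]),
       modules_used = per$module[ok])
}
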