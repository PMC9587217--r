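# End-to-end pipeline on synthetic sessions: simulate -> connectivity ->
# multilayer modules -> geometry -> decoding -> boundary analyses, with a
# single resolved configuration and deterministic per-stage seeds.

#' Default pipeline configuration
#'
#' All stage parameters in one serializable list. The defaults reproduce the
#' reference recording conditions emulated by the synthetic generator: an
#' 8 x 8 array at 0.4 mm pitch, 4 planted modules of ~1.3 mm diameter, 3 sessions of twenty
#' 5-s blocks at 1 kHz, gamma-weighted within-module coupling with 3x the
#' across-module strength, Bonferroni-thresholded GC networks, multilayer
#' modularity at gamma = 1 with 500 Louvain restarts, and the four-category
#' decoding design (240 trials, 20 folds, 50 early-stopping draws).
#'
#' @param seed global integer seed, expanded into per-stage seeds.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    layout = list(rows = 8, cols = 8, pitch = 0.4, drop_corners = FALSE),
    modules = list(n = 4, target_diameter = 1.3),
    var = list(order = 8, fs = 1000,
               within = list(freq = 100, strength = 0.15, density = 0.35),
               across = list(freq = 8, strength = 0.05, density = 0.10),
               noise_sd = 1),
    session = list(n_sessions = 3, n_blocks = 20, block_len = 5),
    gc = list(order = 8, alpha = 0.05, pooling = "pooled",
              nfreq = 512, normalize_spectra = TRUE),
    mlmod = list(gamma = 1, omega_rule = "median", restarts = 500),
    surrogate = list(n = 500, passes = 100, weight_rule = "out_stub"),
    decode = list(n_trials = 240, n_folds = 20, n_early_draws = 50,
                  lr = 0.5, max_iter = 300, patience = 10,
                  units_per_electrode = 1.5, pref_gain = 3,
                  tuning_correlation = 0.8, shuffle_iter = 100,
                  min_trial_frac = 0.5)
  )
}

# Internal: FNV-1a hash of the serialized configuration (provenance tag).
mm_config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Run the analysis pipeline on synthetic sessions
#'
#' Chains the stages on generator output with known ground truth. Stages:
#' `simulate` (layout, planted modules, VAR truth, LFP sessions, spikes),
#' `connectivity` (pooled-block conditional GC per session, Bonferroni
#' thresholding), `modules` (multilayer Louvain partition, stationarity,
#' persistence), `geometry` (diameters, compactness, boundary pairs, GC
#' boundary contrast), `decode` (per-module classifiers with shuffle-within
#' / shuffle-across), `boundary` (response similarity across boundaries).
#' `all` runs everything. Each stage's RNG is seeded deterministically from
#' the global seed, so a full run is reproducible end to end.
#'
#' @param config configuration list from [default_config()].
#' @param stages character vector of stages, or `"all"`.
#' @param out_dir optional directory for artifacts (partition TSV, network
#'   TSVs, resolved config with hash).
#' @param quiet suppress progress messages.
#' @return list of stage results, including `ground_truth` labels, recovered
#'   `partition`, per-layer ARI vs truth, and decode summaries when run.
#' @export
run_pipeline <- function(config = default_config(), stages = "all",
                         out_dir = NULL, quiet = FALSE) {
  all_stages <- c("simulate", "connectivity", "modules", "geometry",
                  "decode", "boundary")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(config = config, config_hash = mm_config_hash(config))

  # --- simulate ---
  say("simulate: planting modules and generating sessions")
  lay <- make_layout(config$layout$rows, config$layout$cols,
                     config$layout$pitch)
  if (isTRUE(config$layout$drop_corners)) lay <- drop_corners(lay)
  map <- plant_modules(lay, config$modules$n, config$modules$target_diameter,
                       seed = mm_child_seed(config$seed, 11))
  truth <- make_var_truth(map, order = config$var$order, fs = config$var$fs,
                          within = config$var$within,
                          across = config$var$across,
                          noise_sd = config$var$noise_sd,
                          seed = mm_child_seed(config$seed, 12))
  sessions <- generate_session_set(truth,
                                   n_sessions = config$session$n_sessions,
                                   n_blocks = config$session$n_blocks,
                                   block_len = config$session$block_len,
                                   seed = mm_child_seed(config$seed, 13))
  res$layout <- lay
  res$ground_truth <- map
  res$truth <- truth
  res$sessions <- sessions
  if (identical(stages, "simulate")) return(res)

  # --- connectivity ---
  if ("connectivity" %in% stages) {
    say("connectivity: conditional GC per session")
    res$networks <- lapply(sessions, function(s) {
      blocks <- as_blockset(s)
      gcm <- conditional_gc_matrix(blocks$blocks, config$gc$order)
      gcm <- gc_significance(gcm, alpha = config$gc$alpha)
      functional_network(gcm, lay, session_id = s$session_id)
    })
    res$connection_probability <-
      vapply(res$networks, connection_probability, numeric(1))
    res$session_similarity <- if (length(res$networks) > 1)
      session_similarity(res$networks) else NULL
  }

  # --- modules ---
  if ("modules" %in% stages) {
    say("modules: multilayer modularity maximization")
    ml <- build_multilayer(res$networks,
                           omega = if (config$mlmod$omega_rule == "median")
                             "median" else config$mlmod$omega)
    part <- louvain_optimize(ml, gamma = config$mlmod$gamma,
                             n_restarts = config$mlmod$restarts,
                             seed = mm_child_seed(config$seed, 31))
    res$multilayer <- ml
    res$partition <- part
    res$Q_ml <- part$Q_ml
    if (ml$n_layers > 1) {
      res$stationarity <- stationarity(part)
      res$persistence <- normalized_persistence(part)
    }
    res$ari <- vapply(seq_len(ml$n_layers), function(s)
      adjusted_rand_index(part$labels[, s], map$labels), numeric(1))
  }

  # --- geometry ---
  if ("geometry" %in% stages) {
    say("geometry: module extent and boundaries")
    lab1 <- res$partition$labels[, 1]
    res$diameter <- module_diameter(lab1, lay)
    res$compactness <- module_compactness(lab1, lay)
    if (length(unique(lab1)) >= 2) {
      res$boundary <- boundary_pairs(lab1, lay)
      res$boundary_gc <- boundary_gc_contrast(res$networks[[1]],
                                              res$boundary)
    }
  }

  # --- decode ---
  if ("decode" %in% stages || "boundary" %in% stages) {
    say("decode: module-tuned spiking and classification")
    dc <- config$decode
    tun <- make_tuning_model(map,
                             n_units = round(dc$units_per_electrode * lay$n),
                             pref_gain = dc$pref_gain,
                             tuning_correlation = dc$tuning_correlation,
                             seed = mm_child_seed(config$seed, 51))
    spk <- generate_spikes(tun, n_trials = dc$n_trials,
                           seed = mm_child_seed(config$seed, 52))
    rates <- transform_rates(spk)
    res$spikes <- spk
    res$rates <- rates
  }
  if ("decode" %in% stages) {
    dc <- config$decode
    part_lab <- res$partition$labels[, 1]
    mods <- sort(unique(part_lab))
    unit_mod <- part_lab[spk_units_electrode(res$spikes, res$rates)]
    decoders <- list()
    for (m in mods) {
      uids <- res$rates$unit_ids[unit_mod == m]
      if (length(uids) < 2) next
      clf <- train_module_classifier(res$rates, uids, mode = "overall",
                                     n_folds = dc$n_folds,
                                     n_early_draws = dc$n_early_draws,
                                     lr = dc$lr, max_iter = dc$max_iter,
                                     patience = dc$patience,
                                     seed = mm_child_seed(config$seed,
                                                          60 + m))
      decoders[[as.character(m)]] <- clf
    }
    res$decoders <- decoders
    if (length(decoders) >= 2) {
      mods_d <- names(decoders)
      sw <- sa <- setNames(numeric(length(mods_d)), mods_d)
      for (i in seq_along(mods_d)) {
        m <- mods_d[i]
        other <- mods_d[if (i == length(mods_d)) 1 else i + 1]
        sw[i] <- shuffle_within_accuracy(decoders[[m]], res$rates,
                                         n_iter = dc$shuffle_iter,
                                         seed = mm_child_seed(config$seed,
                                                              70 + i))$accuracy
        sa[i] <- shuffle_across_accuracy(decoders[[m]], res$rates,
                                         decoders[[other]]$unit_ids,
                                         n_iter = dc$shuffle_iter,
                                         seed = mm_child_seed(config$seed,
                                                              80 + i))$accuracy
      }
      res$shuffle_within <- sw
      res$shuffle_across <- sa
    }
  }

  # --- boundary (response similarity) ---
  if ("boundary" %in% stages && !is.null(res$boundary)) {
    say("boundary: response similarity at module boundaries")
    res$boundary_similarity <-
      boundary_response_similarity(res$rates, res$boundary,
                                   min_trial_frac =
                                     config$decode$min_trial_frac)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- config
    cfg$hash <- res$config_hash
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$partition))
      write_partition_tsv(res$partition,
                          file.path(out_dir, "partition.tsv"))
    jsonlite::write_json(list(labels = map$labels,
                              n_modules = map$n_modules),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

# Internal: electrode index of each unit retained in the rate tensor.
spk_units_electrode <- function(spk, rates) {
  spk$units$electrode[match(rates$unit_ids, spk$units$unit_id)]
}
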