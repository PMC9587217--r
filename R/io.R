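# Plain-text interchange: session containers (CSV matrix + JSON metadata),
# spike/trial CSVs, network and partition TSVs, ground-truth JSON.

#' Write a session to a directory of plain-text files
#'
#' Layout: `lfp.csv` (channels x samples, no header), `meta.json` (sampling
#' rate, session id, electrode coordinates, block structure), and when
#' present `truth.json` (planted ground truth summary).
#'
#' @param session an `mm_session`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "mm_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(format(session$lfp, digits = 8, trim = TRUE, scientific = TRUE),
              file.path(dir, "lfp.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  meta <- list(session_id = session$session_id, fs = session$fs,
               n_channels = nrow(session$lfp),
               n_samples = ncol(session$lfp),
               block_len = session$block_len, n_blocks = session$n_blocks,
               layout = list(rows = session$layout$rows,
                             cols = session$layout$cols,
                             pitch = session$layout$pitch),
               coords = session$layout$coords)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(session$truth)) {
    tr <- session$truth
    jsonlite::write_json(list(order = tr$order,
                              labels = tr$map$labels,
                              n_modules = tr$map$n_modules,
                              spectral_radius = tr$spectral_radius,
                              edges = tr$edges),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing `lfp.csv` and `meta.json`.
#' @return an `mm_session` (without generating truth unless stored).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lfp <- as.matrix(read.table(file.path(dir, "lfp.csv"), sep = ","))
  dimnames(lfp) <- NULL
  layout <- make_layout(meta$layout$rows, meta$layout$cols, meta$layout$pitch)
  if (nrow(layout$coords) != meta$n_channels) {
    layout$coords <- as.matrix(meta$coords)
    layout$n <- meta$n_channels
  }
  structure(list(lfp = lfp, fs = meta$fs, layout = layout,
                 block_len = meta$block_len, n_blocks = meta$n_blocks,
                 session_id = meta$session_id,
                 retained_channels = seq_len(meta$n_channels)),
            class = "mm_session")
}

#' Write spike and trial tables as CSV
#'
#' `spikes.csv` has columns `unit_id,spike_time_s`; `trials.csv` has
#' `trial,onset_s,category,correct`; `units.csv` maps units to electrodes.
#'
#' @param spk an `mm_spikes`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_spikes <- function(spk, dir) {
  stopifnot(inherits(spk, "mm_spikes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(spk$spikes, file.path(dir, "spikes.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(spk$trials, file.path(dir, "trials.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(spk$units, file.path(dir, "units.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(spk$baseline, file.path(dir, "baseline.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a functional network as a TSV edge table
#'
#' Columns: source, target, F, p, significant (one row per ordered pair
#' with nonzero or significant weight; `all = TRUE` writes every pair).
#'
#' @param gcm an `mm_gc` (ideally after [gc_significance()]).
#' @param path output file.
#' @param all write all ordered pairs (default FALSE: nonzero only).
#' @return the path, invisibly.
#' @export
write_network_tsv <- function(gcm, path, all = FALSE) {
  K <- gcm$K
  src <- rep(seq_len(K), times = K)
  tgt <- rep(seq_len(K), each = K)
  off <- src != tgt
  df <- data.frame(source = src[off], target = tgt[off],
                   F = gcm$F[cbind(src[off], tgt[off])],
                   p = if (!is.null(gcm$pvals))
                     gcm$pvals[cbind(src[off], tgt[off])] else NA_real_,
                   significant = if (!is.null(gcm$mask))
                     gcm$mask[cbind(src[off], tgt[off])] else NA)
  if (!all && !is.null(gcm$mask)) df <- df[df$significant, ]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a multilayer partition as TSV
#'
#' Columns: electrode, layer, community.
#'
#' @param part an `mm_partition`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_partition_tsv <- function(part, path) {
  stopifnot(inherits(part, "mm_partition"))
  df <- data.frame(electrode = rep(seq_len(nrow(part$labels)),
                                   ncol(part$labels)),
                   layer = rep(seq_len(ncol(part$labels)),
                               each = nrow(part$labels)),
                   community = as.integer(part$labels))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
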