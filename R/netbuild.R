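# Per-session functional networks, cross-session similarity, and
# degree-matched directed surrogate ensembles.

#' Assemble a functional network from a thresholded GC matrix
#'
#' @param gcm an `mm_gc` that has been through [gc_significance()] (or any
#'   `mm_gc`; the raw F matrix is used if no threshold is present).
#' @param layout the electrode `mm_layout`.
#' @param session_id session label.
#' @return an object of class `mm_network`: `adjacency` (K x K,
#'   `adjacency[i, j]` = weight of directed edge i -> j), `layout`,
#'   `session_id`.
#' @export
functional_network <- function(gcm, layout, session_id = "session") {
  A <- if (!is.null(gcm$thresholded)) gcm$thresholded else gcm$F
  stopifnot(nrow(A) == layout$n)
  structure(list(adjacency = A, layout = layout, session_id = session_id),
            class = "mm_network")
}

#' @export
print.mm_network <- function(x, ...) {
  cat(sprintf("mm_network '%s': %d nodes, connection probability %.3f\n",
              x$session_id, nrow(x$adjacency), connection_probability(x)))
  invisible(x)
}

#' Connection probability of a directed network
#'
#' Fraction of ordered node pairs carrying a nonzero edge.
#'
#' @param net an `mm_network` or adjacency matrix.
#' @return scalar in [0, 1].
#' @export
connection_probability <- function(net) {
  A <- if (inherits(net, "mm_network")) net$adjacency else net
  N <- nrow(A)
  offdiag <- A[row(A) != col(A)]
  sum(offdiag != 0) / (N * (N - 1))
}

#' Cross-session adjacency similarity
#'
#' Pearson correlation between the vectorized off-diagonal adjacency entries
#' (zeros included) of every pair of session networks; the sparsity pattern
#' is part of network identity.
#'
#' @param nets list of `mm_network` objects over the same node set.
#' @return list with `matrix` (session x session correlations, unit
#'   diagonal) and `mean` over distinct pairs.
#' @export
session_similarity <- function(nets) {
  if (length(nets) < 2) stop("need at least 2 sessions")
  Ns <- vapply(nets, function(n) nrow(n$adjacency), numeric(1))
  if (length(unique(Ns)) != 1) stop("sessions have mismatched node sets")
  vecs <- vapply(nets, function(n) {
    A <- n$adjacency
    A[row(A) != col(A)]
  }, numeric(Ns[1] * (Ns[1] - 1)))
  cm <- stats::cor(vecs)
  list(matrix = cm, mean = mean(cm[upper.tri(cm)]))
}

#' Degree-matched directed surrogate ensemble
#'
#' Randomizes a weighted directed network by repeated double-edge swaps
#' `(a -> b, c -> d) => (a -> d, c -> b)`, rejecting swaps that would create
#' self-loops or multi-edges, so that every node's in-degree and out-degree
#' are preserved exactly. Edge weights travel with the out-going (source)
#' endpoint. One pass attempts `|E|` swaps.
#'
#' @param net an `mm_network`.
#' @param n number of surrogate networks (default 500).
#' @param passes swap passes per surrogate (default 100).
#' @param seed integer seed.
#' @return an object of class `mm_surrogates`: list of `mm_network`
#'   surrogates plus the generation settings.
#' @export
degree_matched_surrogates <- function(net, n = 500, passes = 100,
                                      seed = NULL) {
  stopifnot(inherits(net, "mm_network"))
  A <- net$adjacency
  N <- nrow(A)
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  if (nrow(idx) < 2) {
    warning("fewer than 2 edges; surrogates are copies of the input")
    surr <- replicate(n, net, simplify = FALSE)
    return(structure(list(networks = surr, n = n, passes = passes,
                          seed = seed), class = "mm_surrogates"))
  }
  w <- A[idx]
  if (is.null(seed)) seed <- mm_with_seed(NULL, sample.int(2^30, 1))
  res <- mm_edge_swap_cpp(idx[, 1] - 1L, idx[, 2] - 1L, w, N, n, passes,
                          as.integer(seed))
  surr <- lapply(seq_len(n), function(s) {
    el <- res[[s]]
    As <- matrix(0, N, N)
    As[cbind(el$from + 1L, el$to + 1L)] <- el$weight
    structure(list(adjacency = As, layout = net$layout,
                   session_id = paste0(net$session_id, "_surr", s)),
              class = "mm_network")
  })
  structure(list(networks = surr, n = n, passes = passes, seed = seed),
            class = "mm_surrogates")
}

# Internal: in- and out-degree sequences of an adjacency matrix.
mm_degrees <- function(A) {
  nz <- A != 0 & row(A) != col(A)
  list(out = rowSums(nz), `in` = colSums(nz))
}
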