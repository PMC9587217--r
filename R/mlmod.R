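# Multilayer (temporal) network construction, multilayer modularity (with
# the directed Leicht-Newman per-layer null), generalized Louvain
# optimization, and partition stability measures.

#' Build a multilayer temporal network from session networks
#'
#' Stacks per-session adjacency layers chronologically and couples each node
#' to itself in the adjacent layers with uniform interlayer weight `omega`
#' (diagonal-ordinal-uniform coupling). By default `omega` is the median
#' nonzero intra-layer weight across all sessions, so interlayer links are of
#' the same order as the functional weights.
#'
#' @param nets list of `mm_network` objects (chronological order).
#' @param omega interlayer coupling; `"median"` (default) or a number.
#' @return an object of class `mm_multilayer`: `layers` (list of adjacency
#'   matrices), `omega`, `n_nodes`, `n_layers`, `layout`.
#' @export
build_multilayer <- function(nets, omega = "median") {
  stopifnot(length(nets) >= 1)
  layers <- lapply(nets, function(n)
    if (inherits(n, "mm_network")) n$adjacency else n)
  N <- nrow(layers[[1]])
  if (!all(vapply(layers, nrow, 0L) == N)) stop("layers differ in node count")
  if (identical(omega, "median")) {
    nz <- unlist(lapply(layers, function(A) A[A != 0 & row(A) != col(A)]))
    if (length(nz) == 0) {
      warning("no nonzero weights in any layer; omega set to 0")
      omega <- 0
    } else omega <- median(nz)
  }
  layout <- if (inherits(nets[[1]], "mm_network")) nets[[1]]$layout else NULL
  structure(list(layers = layers, omega = omega, n_nodes = N,
                 n_layers = length(layers), layout = layout),
            class = "mm_multilayer")
}

# Internal: full (unsymmetrized) multilayer modularity contribution matrix C
# over node-layer pairs (u = (s - 1) * N + i) and the normalization mu.
# C[u, v] = (A_s[i, j] - gamma * k_out_i * k_in_j / m_s) for same-layer
# pairs, + omega on diagonal-ordinal interlayer links. mu counts all
# intra-layer weight once per ordered edge and each interlayer link in both
# directions, matching the double appearance of the omega term in the sum.
mm_modularity_matrix <- function(mlnet, gamma = 1) {
  N <- mlnet$n_nodes; S <- mlnet$n_layers
  NS <- N * S
  C <- matrix(0, NS, NS)
  mu <- 0
  for (s in seq_len(S)) {
    A <- mlnet$layers[[s]]
    m_s <- sum(A)
    kout <- rowSums(A)
    kin <- colSums(A)
    P <- if (m_s > 0) outer(kout, kin) / m_s else matrix(0, N, N)
    rows <- ((s - 1) * N + 1):(s * N)
    C[rows, rows] <- A - gamma * P
    mu <- mu + m_s
  }
  if (S > 1 && mlnet$omega != 0) {
    for (s in seq_len(S - 1)) {
      a <- ((s - 1) * N + 1):(s * N)
      b <- (s * N + 1):((s + 1) * N)
      C[cbind(a, b)] <- C[cbind(a, b)] + mlnet$omega
      C[cbind(b, a)] <- C[cbind(b, a)] + mlnet$omega
    }
  }
  mu <- mu + 2 * mlnet$omega * N * (S - 1)
  list(C = C, mu = mu)
}

#' Multilayer modularity of a partition
#'
#' Evaluates the multilayer quality function
#' `Q = (1/mu) * sum_{ijst} [(A_ijs - gamma P_ijs) delta_st +
#' delta_ij omega_jst] delta(c_is, c_jt)`, with the directed Leicht-Newman
#' null `P_ijs = k_i^out(s) k_j^in(s) / m_s` per layer (interlayer links
#' enter only through the omega term) and `mu` the total weight of all
#' intra- and inter-layer edges. Bounded above by 1.
#'
#' @param mlnet an `mm_multilayer`.
#' @param labels N x S integer matrix (or length-N*S vector, layer-major) of
#'   community assignments per node-layer pair.
#' @param gamma resolution parameter (default 1).
#' @return scalar quality `Q_ml`.
#' @export
quality <- function(mlnet, labels, gamma = 1) {
  stopifnot(inherits(mlnet, "mm_multilayer"))
  lab <- as.integer(labels)
  NS <- mlnet$n_nodes * mlnet$n_layers
  stopifnot(length(lab) == NS)
  mm <- mm_modularity_matrix(mlnet, gamma)
  same <- outer(lab, lab, "==")
  sum(mm$C[same]) / mm$mu
}

#' Maximize multilayer modularity with generalized Louvain
#'
#' Treats node-layer pairs as super-nodes of a single modularity matrix and
#' runs the Louvain heuristic (greedy moves in random order, then
#' aggregation, to convergence). The algorithm is stochastic; `n_restarts`
#' independent restarts are performed (each seeded from `seed` and its
#' restart index) and the best partition is returned together with all
#' restart qualities. Community labels are shared across layers by
#' construction, so modules can be tracked over time.
#'
#' @inheritParams quality
#' @param n_restarts number of Louvain restarts (default 500).
#' @param seed integer seed.
#' @return an object of class `mm_partition`: `labels` (N x S matrix),
#'   `Q_ml`, `gamma`, `restart_qualities`, `n_modules`.
#' @export
louvain_optimize <- function(mlnet, gamma = 1, n_restarts = 500,
                             seed = NULL) {
  stopifnot(inherits(mlnet, "mm_multilayer"))
  mm <- mm_modularity_matrix(mlnet, gamma)
  B <- (mm$C + t(mm$C)) / 2
  if (is.null(seed)) seed <- mm_with_seed(NULL, sample.int(2^30, 1))
  res <- mm_louvain_cpp(B, as.integer(n_restarts), as.integer(seed))
  labels <- matrix(as.integer(res$labels), mlnet$n_nodes, mlnet$n_layers)
  # canonical label order: by first appearance
  labels[] <- match(labels, unique(as.integer(labels)))
  q <- quality(mlnet, labels, gamma)
  structure(list(labels = labels, Q_ml = q, gamma = gamma,
                 restart_qualities = res$totals / mm$mu,
                 n_modules = length(unique(as.integer(labels))),
                 omega = mlnet$omega, seed = seed),
            class = "mm_partition")
}

#' @export
print.mm_partition <- function(x, ...) {
  cat(sprintf("mm_partition: %d modules, %d nodes x %d layers, Q_ml = %.4f\n",
              x$n_modules, nrow(x$labels), ncol(x$labels), x$Q_ml))
  invisible(x)
}

#' Exhaustive maximum of the multilayer quality function
#'
#' Brute-force search over all set partitions of the node-layer pairs
#' (restricted-growth enumeration); feasible only for very small instances
#' (up to about 13 node-layer pairs). Serves as the exact oracle for the
#' Louvain heuristic.
#'
#' @inheritParams quality
#' @return list with `Q_ml` (the exact maximum) and `labels` (N x S matrix).
#' @export
exhaustive_max_quality <- function(mlnet, gamma = 1) {
  stopifnot(inherits(mlnet, "mm_multilayer"))
  mm <- mm_modularity_matrix(mlnet, gamma)
  B <- (mm$C + t(mm$C)) / 2
  res <- mm_exhaustive_cpp(B)
  labels <- matrix(as.integer(res$labels), mlnet$n_nodes, mlnet$n_layers)
  list(Q_ml = res$best_total / mm$mu, labels = labels)
}

#' Partition stationarity across consecutive layers
#'
#' Similarity of the partitions in consecutive layers, measured as the
#' Jaccard index of co-classification: the number of node pairs co-assigned
#' in both layers over the number co-assigned in either; averaged over all
#' consecutive layer pairs.
#'
#' @param part an `mm_partition` (or N x S label matrix).
#' @return scalar in [0, 1].
#' @export
stationarity <- function(part) {
  labels <- if (inherits(part, "mm_partition")) part$labels else part
  S <- ncol(labels)
  if (S < 2) stop("stationarity requires at least 2 layers")
  jac <- vapply(seq_len(S - 1), function(s) {
    a <- outer(labels[, s], labels[, s], "==")
    b <- outer(labels[, s + 1], labels[, s + 1], "==")
    ut <- upper.tri(a)
    inter <- sum(a[ut] & b[ut])
    uni <- sum(a[ut] | b[ut])
    if (uni == 0) 0 else inter / uni
  }, numeric(1))
  mean(jac)
}

#' Normalized persistence of a multilayer partition
#'
#' Fraction of node-layer transitions in which a node keeps its community
#' label: `sum_{s < S} sum_i 1[c_is == c_i,s+1] / (N (S - 1))`.
#'
#' @inheritParams stationarity
#' @return scalar in [0, 1].
#' @export
normalized_persistence <- function(part) {
  labels <- if (inherits(part, "mm_partition")) part$labels else part
  S <- ncol(labels)
  if (S < 2) stop("persistence requires at least 2 layers")
  mean(labels[, -S] == labels[, -1])
}

#' Compare partition metrics against a surrogate ensemble
#'
#' Optimizes each surrogate's multilayer network with the same settings as
#' the real network and evaluates a set of partition metrics on each,
#' returning the surrogate distributions alongside the real values for
#' paired or percentile comparisons.
#'
#' @param nets list of real `mm_network` session layers.
#' @param surrogate_sets list (one element per session) of `mm_surrogates`
#'   with equal `n`; surrogate multilayer `k` stacks the `k`-th surrogate of
#'   every session.
#' @param gamma,n_restarts,seed optimization settings (applied identically
#'   to real and surrogate networks).
#' @param metrics which metrics to evaluate.
#' @return list with `real` (named metric values) and `surrogate`
#'   (matrix: surrogate x metric).
#' @export
compare_to_surrogates <- function(nets, surrogate_sets, gamma = 1,
                                  n_restarts = 100, seed = NULL,
                                  metrics = c("Q_ml", "stationarity",
                                              "persistence", "diameter",
                                              "compactness")) {
  stopifnot(length(surrogate_sets) == length(nets))
  n_surr <- unique(vapply(surrogate_sets, function(s) length(s$networks), 0L))
  stopifnot(length(n_surr) == 1)
  if (n_surr == 0) stop("empty surrogate ensemble")
  layout <- nets[[1]]$layout

  eval_metrics <- function(net_list, sd_) {
    ml <- build_multilayer(net_list)
    part <- louvain_optimize(ml, gamma = gamma, n_restarts = n_restarts,
                             seed = sd_)
    out <- c()
    if ("Q_ml" %in% metrics) out["Q_ml"] <- part$Q_ml
    if ("stationarity" %in% metrics && ml$n_layers > 1)
      out["stationarity"] <- stationarity(part)
    if ("persistence" %in% metrics && ml$n_layers > 1)
      out["persistence"] <- normalized_persistence(part)
    if (("diameter" %in% metrics || "compactness" %in% metrics) &&
        !is.null(layout)) {
      dia <- comp <- numeric(0)
      for (s in seq_len(ml$n_layers)) {
        lab <- part$labels[, s]
        dia <- c(dia, module_diameter(lab, layout))
        comp <- c(comp, module_compactness(lab, layout))
      }
      if ("diameter" %in% metrics) out["diameter"] <- mean(dia)
      if ("compactness" %in% metrics) out["compactness"] <- mean(comp)
    }
    out
  }

  real <- eval_metrics(nets, mm_child_seed(seed, 0))
  surr <- t(vapply(seq_len(n_surr), function(k) {
    layer_k <- lapply(surrogate_sets, function(s) s$networks[[k]])
    eval_metrics(layer_k, mm_child_seed(seed, k))
  }, real))
  list(real = real, surrogate = surr)
}

#' Random directed weighted multilayer network
#'
#' Small random instances for oracle comparisons: each layer is a directed
#' Erdos-Renyi graph with uniform weights; interlayer coupling follows the
#' median-weight rule.
#'
#' @param n_nodes,n_layers dimensions.
#' @param density edge probability per ordered pair.
#' @param seed integer seed.
#' @return an `mm_multilayer`.
#' @export
random_multilayer <- function(n_nodes = 6, n_layers = 2, density = 0.5,
                              seed = NULL) {
  layers <- mm_with_seed(seed, {
    lapply(seq_len(n_layers), function(s) {
      A <- matrix(runif(n_nodes^2), n_nodes, n_nodes) *
        (matrix(runif(n_nodes^2), n_nodes, n_nodes) < density)
      diag(A) <- 0
      A
    })
  })
  build_multilayer(layers)
}
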