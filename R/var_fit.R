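# Multi-realization VAR fitting: lagged least squares pooled across blocks,
# never regressing across block boundaries.

# Internal: accumulate pooled moment matrices over blocks.
# Predictor ordering: column (k - 1) * K + j holds channel j at lag k.
mm_var_moments <- function(blocks, order, demean = TRUE) {
  stopifnot(order >= 1)
  K <- nrow(blocks[[1]])
  Kp <- K * order
  ZtZ <- matrix(0, Kp, Kp)
  ZtY <- matrix(0, Kp, K)
  YtY <- matrix(0, K, K)
  n_eff <- 0L
  for (blk in blocks) {
    T_ <- ncol(blk)
    if (T_ <= order) stop("block shorter than the VAR order")
    x <- t(blk)
    if (demean) x <- sweep(x, 2, colMeans(x))
    Y <- x[(order + 1):T_, , drop = FALSE]
    Z <- do.call(cbind, lapply(seq_len(order), function(k) {
      x[(order + 1 - k):(T_ - k), , drop = FALSE]
    }))
    ZtZ <- ZtZ + crossprod(Z)
    ZtY <- ZtY + crossprod(Z, Y)
    YtY <- YtY + crossprod(Y)
    n_eff <- n_eff + (T_ - order)
  }
  list(ZtZ = ZtZ, ZtY = ZtY, YtY = YtY, n_eff = n_eff, K = K, order = order)
}

#' Fit a vector autoregression across multiple data blocks
#'
#' Least-squares VAR estimation that pools lagged moment matrices across
#' blocks (multi-realization fitting), so that no regression ever spans a
#' block boundary. Blocks are demeaned channel-wise before fitting.
#'
#' @param blocks an `mm_blockset` or plain list of channels x samples
#'   matrices.
#' @param order VAR model order `p` (at least 1).
#' @return an object of class `mm_var`: `coeffs` `[K, K, p]` (target-row
#'   convention), `residual_cov`, `n_effective`, `order`, plus the pooled
#'   moment matrices used downstream by the Granger computations.
#' @export
fit_var <- function(blocks, order) {
  if (inherits(blocks, "mm_blockset")) blocks <- blocks$blocks
  if (order < 1) stop("VAR order must be at least 1")
  mom <- mm_var_moments(blocks, order)
  K <- mom$K; Kp <- K * order
  if (mom$n_eff < 10 * Kp)
    warning("fewer than 10 samples per VAR parameter; estimates may be noisy")
  R <- tryCatch(chol(mom$ZtZ), error = function(e)
    stop("ill-conditioned moment matrix; lower the order or use fewer channels"))
  if (min(diag(R))^2 < 1e-12 * max(diag(R))^2)
    stop("ill-conditioned moment matrix; lower the order or use fewer channels")
  Ginv <- chol2inv(R)
  B <- Ginv %*% mom$ZtY
  rss <- diag(mom$YtY) - colSums(mom$ZtY * B)
  resid_cov <- (mom$YtY - crossprod(mom$ZtY, B)) / mom$n_eff
  resid_cov <- (resid_cov + t(resid_cov)) / 2
  coeffs <- array(0, c(K, K, order))
  for (k in seq_len(order))
    coeffs[, , k] <- t(B[((k - 1) * K + 1):(k * K), , drop = FALSE])
  structure(list(coeffs = coeffs, residual_cov = resid_cov,
                 n_effective = mom$n_eff, order = order, K = K,
                 B = B, Ginv = Ginv, rss = rss),
            class = "mm_var")
}

#' Select the VAR order by AIC
#'
#' Akaike information criterion over pooled multi-realization fits:
#' `log det(Sigma_p) + 2 K^2 p / n`.
#'
#' @inheritParams fit_var
#' @param orders candidate orders (default 1..20).
#' @return list with `order` (the minimizer) and the per-order `aic` values.
#' @export
select_var_order <- function(blocks, orders = 1:20) {
  if (inherits(blocks, "mm_blockset")) blocks <- blocks$blocks
  aic <- vapply(orders, function(p) {
    fit <- fit_var(blocks, p)
    ld <- determinant(fit$residual_cov, logarithm = TRUE)$modulus
    as.numeric(ld) + 2 * fit$K^2 * p / fit$n_effective
  }, numeric(1))
  list(order = orders[which.min(aic)], aic = setNames(aic, orders))
}

#' Pairwise conditional Granger causality matrix
#'
#' For every ordered channel pair (source `j`, target `i`) computes the
#' conditional Granger statistic `F = ln(var(eps') / var(eps))`, where `eps`
#' is the residual of the full VAR predicting `i` from the past of all
#' channels and `eps'` the residual of the reduced model omitting the
#' source's lags (conditioning on all channels besides source and target's
#' own past is retained). The reduced-model residual variance is obtained
#' exactly through the standard partitioned-regression identity, which is
#' numerically identical to re-fitting the reduced regression.
#'
#' @inheritParams fit_var
#' @param fit optionally, a pre-computed `mm_var` for these blocks.
#' @return an object of class `mm_gc`: `F` (K x K, `F[i, j]` = GC from
#'   source `i` to target `j`, zero diagonal), `n_effective`, `order`.
#' @export
conditional_gc_matrix <- function(blocks, order, fit = NULL) {
  if (is.null(fit)) fit <- fit_var(blocks, order)
  K <- fit$K; p <- fit$order
  F_ <- matrix(0, K, K)
  for (i in seq_len(K)) {
    rss_full <- fit$rss[i]
    for (j in seq_len(K)) {
      if (i == j) next
      idx <- j + K * (0:(p - 1))
      beta <- fit$B[idx, i]
      M <- fit$Ginv[idx, idx, drop = FALSE]
      d_rss <- sum(beta * solve(M, beta))
      F_[j, i] <- log1p(max(d_rss, 0) / rss_full)
    }
  }
  structure(list(F = F_, n_effective = fit$n_effective, order = p, K = K),
            class = "mm_gc")
}

#' Significance thresholding of a GC matrix
#'
#' Large-sample null: `n * F` is chi-squared with `p` (the VAR order)
#' degrees of freedom for each ordered pair. A Bonferroni correction over the
#' `N (N - 1)` ordered pairs controls the family-wise error rate;
#' non-significant entries are set exactly to zero while significant entries
#' keep their raw `F` value.
#'
#' @param gcm an `mm_gc` from [conditional_gc_matrix()].
#' @param alpha family-wise significance level (default 0.05).
#' @return the `mm_gc` augmented with `pvals`, `mask` (logical significant)
#'   and `thresholded` (F with non-significant entries zeroed).
#' @export
gc_significance <- function(gcm, alpha = 0.05) {
  stopifnot(inherits(gcm, "mm_gc"))
  K <- gcm$K
  pv <- pchisq(gcm$n_effective * gcm$F, df = gcm$order, lower.tail = FALSE)
  diag(pv) <- NA_real_
  n_tests <- K * (K - 1)
  mask <- !is.na(pv) & (pv * n_tests <= alpha)
  thr <- gcm$F
  thr[!mask] <- 0
  gcm$pvals <- pv
  gcm$mask <- mask
  gcm$thresholded <- thr
  gcm$alpha <- alpha
  gcm
}
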