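// Wilson's algorithm for spectral matrix factorization and the inner loop of
// the Geweke conditional spectral Granger decomposition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// "Plus" operator: retain the causal part of a matrix function given on the
// full frequency circle (nfft points). Lag-0 coefficient is halved with its
// strictly lower triangle zeroed (upper-triangular convention matching the
// Cholesky initialization).
static cx_cube plus_operator(const cx_cube& g) {
  const uword k = g.n_rows, nfft = g.n_slices;
  // move to lag domain: ifft along the frequency dimension, per entry
  cx_mat G(nfft, k * k);
  for (uword m = 0; m < nfft; ++m) {
    const cx_mat& s = g.slice(m);
    G.row(m) = vectorise(s).st();
  }
  cx_mat lag = ifft(G);  // column-wise ifft: rows are lags 0..nfft-1
  // zero negative lags (rows nfft/2+1 .. nfft-1)
  for (uword r = nfft / 2 + 1; r < nfft; ++r) lag.row(r).zeros();
  // halve lag 0 and keep only its upper triangle (incl. diagonal)
  cx_mat b0 = reshape(lag.row(0).st(), k, k);
  b0 *= 0.5;
  b0 = trimatu(b0);
  lag.row(0) = vectorise(b0).st();
  cx_mat back = fft(lag);
  cx_cube out(k, k, nfft);
  for (uword m = 0; m < nfft; ++m)
    out.slice(m) = reshape(back.row(m).st(), k, k);
  return out;
}

// [[Rcpp::export]]
Rcpp::List mm_wilson_cpp(const arma::cx_cube& S, int maxit, double tol) {
  const uword k = S.n_rows, nfft = S.n_slices;

  // lag-0 autocovariance = mean of S over the full circle
  cx_mat gam0(k, k, fill::zeros);
  for (uword m = 0; m < nfft; ++m) gam0 += S.slice(m);
  gam0 /= (double)nfft;
  mat g0 = real(gam0);
  g0 = 0.5 * (g0 + g0.t());
  mat h;
  if (!chol(h, g0))  // upper triangular: g0 = h' h
    Rcpp::stop("spectral factorization: lag-0 covariance not positive definite");

  cx_cube psi(k, k, nfft);
  for (uword m = 0; m < nfft; ++m) psi.slice(m) = cx_mat(h.t(), mat(k, k, fill::zeros));

  const cx_mat I_k = cx_mat(eye(k, k), mat(k, k, fill::zeros));
  double err = datum::inf;
  int it = 0;
  cx_cube g(k, k, nfft);
  for (it = 0; it < maxit; ++it) {
    for (uword m = 0; m < nfft; ++m) {
      cx_mat inv_psi = inv(psi.slice(m));
      g.slice(m) = inv_psi * S.slice(m) * inv_psi.t() + I_k;
    }
    cx_cube gp = plus_operator(g);
    double num = 0.0, den = 0.0;
    for (uword m = 0; m < nfft; ++m) {
      cx_mat psinew = psi.slice(m) * gp.slice(m);
      num += accu(square(abs(psinew - psi.slice(m))));
      den += accu(square(abs(psi.slice(m))));
      psi.slice(m) = psinew;
    }
    err = std::sqrt(num / den);
    if (err < tol) break;
  }

  // zero-lag coefficient A0: psi = A0 + A1 z + ...; Sigma = A0 A0'
  cx_mat a0c(k, k, fill::zeros);
  for (uword m = 0; m < nfft; ++m) a0c += psi.slice(m);
  a0c /= (double)nfft;
  mat A0 = real(a0c);
  mat Sigma = A0 * A0.t();

  return Rcpp::List::create(Rcpp::_["psi"] = psi, Rcpp::_["A0"] = A0,
                            Rcpp::_["Sigma"] = Sigma,
                            Rcpp::_["iterations"] = it + 1,
                            Rcpp::_["rel_err"] = err);
}

// Conditional spectral GC from source channel j to all other channels, given
// the full-model transfer function and the reduced-model (source omitted)
// minimum-phase transfer from the Wilson factorization.
//
// H:      K x K x nf full-model transfer (evaluation grid, 0..pi)
// Sigma:  K x K full-model innovation covariance
// Gred:   (K-1) x (K-1) x nf reduced-model transfer
// Sigma2: (K-1) x (K-1) reduced-model innovation covariance
// j:      1-based source index
// Returns K x nf matrix f[i, m] = f_{j -> i | rest}(omega_m); row j is zero.
// [[Rcpp::export]]
arma::mat mm_cond_sgc_cpp(const arma::cx_cube& H, const arma::mat& Sigma,
                          const arma::cx_cube& Gred, const arma::mat& Sigma2,
                          int j) {
  const uword K = H.n_rows, nf = H.n_slices;
  const uword js = (uword)(j - 1);

  uvec rest(K - 1);
  for (uword v = 0, w = 0; v < K; ++v)
    if (v != js) rest(w++) = v;

  // innovation partition: y = source innovation, rest = the others
  mat Sig_rr = Sigma.submat(rest, rest);
  vec c_ry = Sigma.submat(rest, uvec{js});
  vec w_ry = solve(Sig_rr, c_ry);  // Sigma_rr^{-1} Sigma_ry

  mat f(K, nf, fill::zeros);
  cx_mat Ghat(K, K);
  for (uword m = 0; m < nf; ++m) {
    Ghat.zeros();
    Ghat(js, js) = cx_double(1.0, 0.0);
    Ghat.submat(rest, rest) = Gred.slice(m);
    cx_mat Q = solve(Ghat, H.slice(m));  // Ghat^{-1} H
    for (uword t = 0; t < K - 1; ++t) {
      uword i = rest(t);
      cx_rowvec q = Q.row(i);
      cx_double qy = q(js);
      cx_rowvec qrest(K - 1);
      for (uword v = 0; v < K - 1; ++v) qrest(v) = q(rest(v));
      // fold the source innovation's correlated part into the rest
      cx_rowvec qtil = qrest + qy * conv_to<cx_rowvec>::from(w_ry.t());
      double intrinsic = std::real(
          as_scalar(qtil * cx_mat(Sig_rr, mat(size(Sig_rr), fill::zeros)) *
                    qtil.t()));
      double s2 = Sigma2(t, t);
      f(i, m) = std::log(s2 / intrinsic);
    }
  }
  return f;
}
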