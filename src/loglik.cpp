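// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Rotated-basis Gaussian log-likelihood for a Kronecker-structured
// multivariate variance-component model.
//
// After rotating the n x k phenotype matrix Y into the eigenbasis of the
// GRM (Ytil = U' Y, G = U diag(d) U'), rows of Ytil are independent with
//   Cov(ytil_i) = CG * d_i + CX * sqrt(d_i) + CI
// where CG is the k x k coefficient of the G kernel (genetic), CI of the
// identity kernel (residual), and CX of the G^{1/2} kernel (the symmetric
// gene-environment cross term; zero without rGE).
//
// Returns -Inf when any per-row covariance fails the Cholesky factorisation
// (the optimiser treats that as rejection of the parameter point).

// In-place lower Cholesky of the k x k matrix S (column-major); returns
// false if a pivot is not strictly positive. Hand-rolled: k is tiny (<= ~8)
// and LAPACK call overhead dominates at these sizes.
static bool chol_small(double* S, int k) {
  for (int j = 0; j < k; ++j) {
    double piv = S[j + j * k];
    for (int t = 0; t < j; ++t) piv -= S[j + t * k] * S[j + t * k];
    if (piv <= 0.0 || !std::isfinite(piv)) return false;
    piv = std::sqrt(piv);
    S[j + j * k] = piv;
    for (int i = j + 1; i < k; ++i) {
      double v = S[i + j * k];
      for (int t = 0; t < j; ++t) v -= S[i + t * k] * S[j + t * k];
      S[i + j * k] = v / piv;
    }
  }
  return true;
}

// [[Rcpp::export]]
double ll_eigen_cpp(const arma::mat& Ytil, const arma::vec& d,
                    const arma::mat& CG, const arma::mat& CX,
                    const arma::mat& CI) {
  const int n = Ytil.n_rows, k = Ytil.n_cols;
  const double log2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  std::vector<double> S(k * k), z(k);
  const bool has_cross = arma::any(arma::vectorise(CX) != 0.0);
  const double* cg = CG.memptr();
  const double* cx = CX.memptr();
  const double* ci = CI.memptr();
  for (int i = 0; i < n; ++i) {
    const double di = d(i);
    if (has_cross) {
      const double sdi = di > 0.0 ? std::sqrt(di) : 0.0;
      for (int t = 0; t < k * k; ++t) S[t] = cg[t] * di + cx[t] * sdi + ci[t];
    } else {
      for (int t = 0; t < k * k; ++t) S[t] = cg[t] * di + ci[t];
    }
    if (!chol_small(S.data(), k)) return -arma::datum::inf;
    double logdet = 0.0;
    for (int j = 0; j < k; ++j) logdet += std::log(S[j + j * k]);
    // forward solve L z = y_i
    double quad = 0.0;
    for (int j = 0; j < k; ++j) {
      double v = Ytil(i, j);
      for (int t = 0; t < j; ++t) v -= S[j + t * k] * z[t];
      z[j] = v / S[j + j * k];
      quad += z[j] * z[j];
    }
    ll += -0.5 * k * log2pi - logdet - 0.5 * quad;
  }
  return ll;
}

// Per-row Cholesky draw in the rotated basis: returns an n x k matrix whose
// row i is L_i Z_i with Cov = CG d_i + CX sqrt(d_i) + CI; Z is n x k of
// standard normals supplied by the caller (so all randomness stays in R).

// [[Rcpp::export]]
arma::mat sim_eigen_cpp(const arma::mat& Z, const arma::vec& d,
                        const arma::mat& CG, const arma::mat& CX,
                        const arma::mat& CI) {
  const arma::uword n = Z.n_rows, k = Z.n_cols;
  arma::mat out(n, k), S(k, k), L(k, k);
  for (arma::uword i = 0; i < n; ++i) {
    const double di = d(i);
    double sdi = di > 0.0 ? std::sqrt(di) : 0.0;
    S = CG * di + CX * sdi + CI;
    if (!arma::chol(L, S, "lower"))
      Rcpp::stop("implied per-row covariance not positive definite (row %d)",
                 (int)(i + 1));
    out.row(i) = (L * Z.row(i).t()).t();
  }
  return out;
}
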