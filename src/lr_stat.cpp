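#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Sum over spots i of the correlation part of an MVN log density:
//   -0.5 * log det(C_i) - 0.5 * u_i' C_i^{-1} u_i
// where u_i is row i of U (residuals standardized by the kernel standard
// deviations) and C_i is the m x m correlation matrix with diagonal
// 1 + jitter and upper-triangular off-diagonals taken from row i of `rho`
// in R's column-major upper.tri order: (1,2),(1,3),(2,3),(1,4),...
// The -m/2 log(2 pi) constant and the log |S_i| scale terms cancel between
// null and alternative models (shared diagonals) and are omitted.
// [[Rcpp::export]]
double sum_corr_loglik(const arma::mat& U, const arma::mat& rho, double jitter) {
  const arma::uword n = U.n_rows, m = U.n_cols;
  if (rho.n_rows != n || rho.n_cols != m * (m - 1) / 2)
    Rcpp::stop("rho has wrong shape");
  arma::mat C(m, m), L;
  arma::vec u(m), w(m);
  double total = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    C.eye(m, m);
    C.diag() += jitter;
    arma::uword k = 0;
    for (arma::uword b = 1; b < m; ++b)
      for (arma::uword a = 0; a < b; ++a, ++k) {
        C(a, b) = rho(i, k);
        C(b, a) = rho(i, k);
      }
    if (!arma::chol(L, C, "lower"))
      Rcpp::stop("singular covariance at spot %d", (int)(i + 1));
    u = U.row(i).t();
    w = arma::solve(arma::trimatl(L), u);
    total += -arma::accu(arma::log(L.diag())) - 0.5 * arma::dot(w, w);
  }
  return total;
}
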