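// Gram-path repeated k-fold cross-validation sweep over model subsets.
//
// For each repeat the full-design cross-products are accumulated per fold;
// a model's training normal equations for fold f are then the totals minus
// fold f's contribution, restricted to the model's columns. The held-out
// sum of squared errors is obtained from the same fold cross-products:
//   SSE_f = y'y_f - 2 b' (X_f'y_f) + b' (X_f'X_f) b
// so no per-row work is needed inside the model loop. Rank-deficient
// training systems fall back to the Moore-Penrose minimum-norm solution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec solve_minnorm(const mat& G, const vec& b) {
  vec beta;
  bool ok = solve(beta, G, b, solve_opts::no_approx + solve_opts::likely_sympd);
  if (!ok || !beta.is_finite()) {
    mat Gi = pinv(G);
    beta = Gi * b;
  }
  return beta;
}

// X: n x P design (column 1 = intercept), y: outcome,
// col_idx: list of 0-based column index vectors, one per model,
// folds: n x R integer matrix of fold ids in 1..k.
// Returns M x R matrix of RMSEp values.
// [[Rcpp::export]]
arma::mat cv_gram_rmse_cpp(const arma::mat& X, const arma::vec& y,
                           const Rcpp::List& col_idx,
                           const arma::imat& folds, int k) {
  const int n = X.n_rows, P = X.n_cols;
  const int M = col_idx.size(), R = folds.n_cols;

  std::vector<uvec> cols(M);
  for (int m = 0; m < M; ++m)
    cols[m] = Rcpp::as<uvec>(col_idx[m]);

  mat out(M, R);
  mat Gtot = X.t() * X;
  vec btot = X.t() * y;

  cube Gf(P, P, k);
  mat bf(P, k);
  vec yyf(k);
  ivec nf(k);

  for (int r = 0; r < R; ++r) {
    Gf.zeros(); bf.zeros(); yyf.zeros(); nf.zeros();
    for (int i = 0; i < n; ++i) {
      int f = folds(i, r) - 1;
      const rowvec xi = X.row(i);
      Gf.slice(f) += xi.t() * xi;
      bf.col(f) += xi.t() * y(i);
      yyf(f) += y(i) * y(i);
      nf(f) += 1;
    }
    for (int m = 0; m < M; ++m) {
      const uvec& c = cols[m];
      double sse = 0.0;
      for (int f = 0; f < k; ++f) {
        if (n - nf(f) < 1)
          Rcpp::stop("degenerate fold: empty training set");
        const vec bfold = bf.col(f);
        const vec bfc = bfold(c);
        mat Gfc = Gf.slice(f)(c, c);
        mat Gtr = Gtot(c, c) - Gfc;
        vec btr = btot(c) - bfc;
        vec beta = solve_minnorm(Gtr, btr);
        double q = yyf(f) - 2.0 * dot(beta, bfc) +
                   as_scalar(beta.t() * Gfc * beta);
        if (q > 0) sse += q;
      }
      out(m, r) = std::sqrt(sse / n);
    }
  }
  return out;
}
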