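// Graphical lasso via blockwise coordinate descent.
//
// Maximizes  log det K - tr(S K) - lambda * ||K||_{1,off}  over positive
// definite K, with an unpenalized diagonal (the convention used throughout
// the regularized partial-correlation network literature).  Each sweep
// solves, for every column j, the lasso subproblem
//     min_b  0.5 b' W11 b - s12' b + lambda ||b||_1
// on the current covariance estimate W, and the precision matrix is
// recovered from the final regression coefficients, so off-diagonal zeros
// are exact (no thresholding).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double lam) {
  if (x > lam)  return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     double tol = 1e-5, int maxit = 500,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const uword p = S.n_rows;
  if (S.n_cols != p) Rcpp::stop("S must be square");

  if (p == 1) {
    mat W(1, 1); W(0, 0) = S(0, 0);
    mat K(1, 1); K(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("K") = K,
                              Rcpp::Named("beta") = mat(1, 1, fill::zeros),
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  mat W = W_init.isNotNull() ? Rcpp::as<mat>(W_init.get()) : mat(S);
  mat B = B_init.isNotNull() ? Rcpp::as<mat>(B_init.get())
                             : mat(p, p, fill::zeros);
  // diagonal is not penalized: w_jj = s_jj throughout
  W.diag() = S.diag();

  double off_mean = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) off_mean += std::abs(S(i, j));
  off_mean /= (p * (p - 1)) / 2.0;
  const double thr = tol * (off_mean > 0 ? off_mean : 1.0);
  const double inner_thr = thr / 10.0;
  const int inner_maxit = 200;

  int it = 0;
  bool converged = false;
  vec beta(p - 1), s12(p - 1), w12(p - 1);
  mat W11(p - 1, p - 1);

  for (it = 1; it <= maxit; ++it) {
    double dw = 0.0;
    for (uword j = 0; j < p; ++j) {
      // partition out row/column j
      uword r = 0;
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        s12(r) = S(k, j);
        beta(r) = B(k, j);
        uword c = 0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          W11(r, c) = W(k, l);
          ++c;
        }
        ++r;
      }
      // lasso on the block by coordinate descent
      for (int in_it = 0; in_it < inner_maxit; ++in_it) {
        double db = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          const double old = beta(k);
          double x = s12(k) - dot(W11.row(k), beta) + W11(k, k) * old;
          const double bk = soft(x, lambda) / W11(k, k);
          if (bk != old) {
            beta(k) = bk;
            db = std::max(db, std::abs(bk - old));
          }
        }
        if (db < inner_thr) break;
      }
      w12 = W11 * beta;
      r = 0;
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        dw = std::max(dw, std::abs(w12(r) - W(k, j)));
        W(k, j) = w12(r);
        W(j, k) = w12(r);
        B(k, j) = beta(r);
        ++r;
      }
    }
    if (dw < thr) { converged = true; break; }
  }

  // precision matrix from the regression coefficients; zeros stay exact
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (uword k = 0; k < p; ++k)
      if (k != j) denom -= W(k, j) * B(k, j);
    const double kjj = 1.0 / denom;
    K(j, j) = kjj;
    for (uword k = 0; k < p; ++k)
      if (k != j && B(k, j) != 0.0) K(k, j) = -B(k, j) * kjj;
  }
  // enforce exact symmetry (keeps exact zeros: both entries are zero or both
  // nonzero at convergence)
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) {
      if (K(i, j) == 0.0 || K(j, i) == 0.0) { K(i, j) = 0.0; K(j, i) = 0.0; }
      else { const double m = 0.5 * (K(i, j) + K(j, i)); K(i, j) = m; K(j, i) = m; }
    }

  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("K") = K,
                            Rcpp::Named("beta") = B,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
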