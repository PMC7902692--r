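// Block coordinate-descent graphical lasso.
//
// Solves max_Theta  log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// by cycling through variables and solving a lasso problem for each column of
// the working covariance W (Friedman-style blockwise updates). The diagonal is
// unpenalized, so diag(W) = diag(S) throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(const arma::mat& S, double lambda, double tol, int max_iter,
               Nullable<NumericMatrix> W_init = R_NilValue,
               Nullable<NumericMatrix> B_init = R_NilValue) {
  const arma::uword p = S.n_rows;
  arma::mat W(p, p), B(p, p, arma::fill::zeros);
  if (W_init.isNotNull()) {
    W = as<arma::mat>(W_init.get());
  } else {
    W = S;
  }
  W.diag() = S.diag();  // diagonal unpenalized
  if (B_init.isNotNull()) B = as<arma::mat>(B_init.get());

  // convergence scale: mean |off-diagonal of S| (fall back to 1 when ~0)
  double s_off = 0.0;
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = 0; j < p; ++j)
      if (i != j) s_off += std::abs(S(i, j));
  const double n_off = static_cast<double>(p * (p - 1));
  double scale = (n_off > 0) ? s_off / n_off : 0.0;
  if (scale < 1e-12) scale = 1.0;
  const double thresh = tol * scale;
  const double inner_tol = 1e-8;
  const int inner_max = 200;

  bool converged = (p == 1);
  int iter = 0;
  for (iter = 0; iter < max_iter && !converged && p > 1; ++iter) {
    double delta = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      // lasso for column j on W11 with warm-started beta
      arma::vec beta(p - 1);
      arma::uvec idx(p - 1);
      arma::uword r = 0;
      for (arma::uword k = 0; k < p; ++k)
        if (k != j) { idx(r) = k; beta(r) = B(k, j); ++r; }
      for (int it = 0; it < inner_max; ++it) {
        double bdelta = 0.0;
        for (arma::uword a = 0; a < p - 1; ++a) {
          const arma::uword k = idx(a);
          double resid = S(k, j);
          for (arma::uword b = 0; b < p - 1; ++b) {
            if (b == a) continue;
            resid -= W(k, idx(b)) * beta(b);
          }
          const double bnew = soft(resid, lambda) / W(k, k);
          bdelta = std::max(bdelta, std::abs(bnew - beta(a)));
          beta(a) = bnew;
        }
        if (bdelta < inner_tol) break;
      }
      // w12 = W11 beta
      for (arma::uword a = 0; a < p - 1; ++a) {
        const arma::uword k = idx(a);
        double w = 0.0;
        for (arma::uword b = 0; b < p - 1; ++b) w += W(k, idx(b)) * beta(b);
        delta += std::abs(w - W(k, j));
        W(k, j) = w;
        W(j, k) = w;
        B(k, j) = beta(a);
      }
    }
    if (delta / n_off < thresh) converged = true;
  }

  // recover Theta from (W, B)
  arma::mat Theta(p, p, arma::fill::zeros);
  if (p == 1) {
    Theta(0, 0) = 1.0 / S(0, 0);
  } else {
    for (arma::uword j = 0; j < p; ++j) {
      double q = W(j, j);
      for (arma::uword k = 0; k < p; ++k)
        if (k != j) q -= W(k, j) * B(k, j);
      const double t22 = 1.0 / q;
      Theta(j, j) = t22;
      for (arma::uword k = 0; k < p; ++k)
        if (k != j) Theta(k, j) = -B(k, j) * t22;
    }
    Theta = 0.5 * (Theta + Theta.t());
  }

  return List::create(_["Theta"] = Theta, _["W"] = W, _["B"] = B,
                      _["iterations"] = iter, _["converged"] = converged);
}
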