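// Graphical lasso: block coordinate descent on the working covariance
// (Friedman-Hastie-Tibshirani scheme), diagonal penalised (W_ii = S_ii + lambda).
// Inner problems are lasso regressions solved by coordinate descent with warm
// starts across sweeps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, int max_iter, double tol) {
  const uword p = S.n_rows;
  mat W = S;
  W.diag() += lambda;
  mat Beta(p - 1, p, fill::zeros);  // per-column lasso coefficients
  const double off_scale = std::max(1e-12, mean(mean(abs(S - diagmat(S.diag())))));
  double resid = 0.0;
  bool converged = false;
  const int inner_max = 200;
  const double inner_tol = 1e-7;

  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W(idx, idx);
      vec s12 = S.col(j); s12 = s12(idx);
      vec beta = Beta.col(j);
      // lasso coordinate descent: 0.5 b'W11 b - b's12 + lambda|b|_1
      for (int ii = 0; ii < inner_max; ++ii) {
        double ch = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double grad = s12(k) - dot(W11.row(k), beta) + W11(k, k) * beta(k);
          double bnew = soft(grad, lambda) / W11(k, k);
          ch = std::max(ch, std::fabs(bnew - beta(k)));
          beta(k) = bnew;
        }
        if (ch < inner_tol) break;
      }
      Beta.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        delta = std::max(delta, std::fabs(W(idx(k), j) - w12(k)));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    resid = delta / off_scale;
    if (resid < tol) { converged = true; break; }
  }

  // recover the precision matrix from the final (W, Beta)
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    vec beta = Beta.col(j);
    vec w12 = W(idx, uvec{j});
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = theta_jj;
    for (uword k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * theta_jj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("precision") = Theta,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("residual") = resid);
}
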