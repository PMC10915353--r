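// L1-penalised Gaussian maximum likelihood (graphical lasso) by block
// coordinate descent: cycle over nodes, solve each node's lasso problem on
// the current working covariance, update that row/column, and recover the
// precision matrix from the final regressions. Benchmark baseline only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S,
                     double rho,
                     arma::mat B,        // (p-1) x p warm-start coefficients
                     int max_sweeps,
                     double tol) {
  const int p = S.n_rows;
  mat W = S;
  W.diag() += rho;

  const double thr = tol * mean(abs(vectorise(S - diagmat(S.diag())) ) + 1e-12);
  bool converged = false;
  int sweep = 0;

  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_dw = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx(p - 1);
      int t = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx(t++) = i;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      // lasso coordinate descent on 0.5 b'W11 b - b's12 + rho|b|_1
      for (int inner = 0; inner < 200; ++inner) {
        double max_db = 0.0;
        for (int l = 0; l < p - 1; ++l) {
          double grad = s12(l) - dot(W11.col(l), beta) + W11(l, l) * beta(l);
          double bnew = 0.0;
          if (grad > rho) bnew = (grad - rho) / W11(l, l);
          else if (grad < -rho) bnew = (grad + rho) / W11(l, l);
          double db = std::abs(bnew - beta(l));
          if (db > max_db) max_db = db;
          beta(l) = bnew;
        }
        if (max_db < 1e-7) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      t = 0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double dw = std::abs(W(i, j) - w12(t));
        if (dw > max_dw) max_dw = dw;
        W(i, j) = w12(t);
        W(j, i) = w12(t);
        ++t;
      }
    }
    if (max_dw < thr) { converged = true; ++sweep; break; }
  }

  // Recover Theta from the final regressions.
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    int t = 0;
    for (int i = 0; i < p; ++i) if (i != j) idx(t++) = i;
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = theta_jj;
    t = 0;
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      Theta(i, j) = -beta(t) * theta_jj;
      ++t;
    }
  }
  Theta = (Theta + Theta.t()) / 2.0;

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("B") = B,
    Rcpp::Named("sweeps") = sweep,
    Rcpp::Named("converged") = converged);
}
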