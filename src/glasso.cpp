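// Blockwise coordinate-descent graphical LASSO.
//
// Minimises  tr(S %*% Theta) - logdet(Theta) + rho * sum_{i != j} |Theta_ij|
// (off-diagonal penalty only) by cycling over columns of the working
// covariance W: each column solve is an L1-penalised quadratic programme
// handled by coordinate descent with soft-thresholding. The precision matrix
// is recovered from the final regression coefficients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double rho, int maxit, double tol,
                     int inner_maxit) {
  const int p = S.n_rows;
  mat W = S;
  mat B(p - 1, p, fill::zeros);
  // convergence threshold on the average absolute off-diagonal of S
  double offsum = accu(abs(S)) - accu(abs(S.diag()));
  double thr = tol * std::max(offsum / std::max(p * (p - 1), 1), 1e-12);

  // per-column index sets (all rows except j)
  std::vector<uvec> idxs(p);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    int c = 0;
    for (int m = 0; m < p; ++m)
      if (m != j) idx(c++) = m;
    idxs[j] = idx;
  }

  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      const uvec& idx = idxs[j];
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);
      for (int ii = 0; ii < inner_maxit; ++ii) {
        double del = 0.0;
        for (int l = 0; l < p - 1; ++l) {
          double old = beta(l);
          double r = s12(l) - dot(W11.row(l), beta) + W11(l, l) * old;
          double b = 0.0;
          if (r > rho) b = (r - rho) / W11(l, l);
          else if (r < -rho) b = (r + rho) / W11(l, l);
          beta(l) = b;
          del = std::max(del, std::abs(b - old));
        }
        if (del < thr * 0.1) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (int c = 0; c < p - 1; ++c) {
        maxdiff = std::max(maxdiff, std::abs(W(idx(c), j) - w12(c)));
        W(idx(c), j) = w12(c);
        W(j, idx(c)) = w12(c);
      }
    }
    if (maxdiff < thr) { converged = true; ++it; break; }
  }

  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    const uvec& idx = idxs[j];
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12(idx);
    double tjj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    for (int c = 0; c < p - 1; ++c)
      Theta(idx(c), j) = -beta(c) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("wi") = Theta,
                            Rcpp::Named("niter") = it,
                            Rcpp::Named("converged") = converged);
}
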