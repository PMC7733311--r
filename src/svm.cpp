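#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft-margin SVM dual solved by maximal-violating-pair SMO (the
// working-set strategy of LIBSVM): maximize sum(alpha) - 1/2 sum alpha_i
// alpha_j y_i y_j K_ij subject to 0 <= alpha <= C, sum alpha_i y_i = 0.
//
// With f_i = sum_j alpha_j y_j K_ij, optimality holds when
//   max_{i in I_up} (y_i - f_i)  -  min_{j in I_low} (y_j - f_j)  <  tol,
// where I_up/I_low are the index sets with room to move the equality
// constraint up/down. The violating pair is updated jointly; the bias b
// is recovered at the end as the midpoint of the final bounds (mean over
// free support vectors when available). Indefinite kernels (sigmoid) get
// a floored curvature so steps stay bounded, and total updates are
// capped by max_updates.
// [[Rcpp::export]]
Rcpp::List svm_smo_cpp(const arma::mat& K, const arma::vec& y, double C,
                       double tol, int max_passes, int max_updates) {
  (void)max_passes;
  const uword N = y.n_elem;
  vec alpha(N, fill::zeros);
  vec f(N, fill::zeros);  // f_i = sum_j alpha_j y_j K_ij
  int updates = 0;
  double m_val = 0, M_val = 0;
  while (updates < max_updates) {
    // maximal violating pair
    sword i = -1, j = -1;
    m_val = -datum::inf;
    M_val = datum::inf;
    for (uword t = 0; t < N; ++t) {
      const double v = y(t) - f(t);
      const bool in_up = (y(t) > 0 && alpha(t) < C - 1e-12) ||
                         (y(t) < 0 && alpha(t) > 1e-12);
      const bool in_low = (y(t) > 0 && alpha(t) > 1e-12) ||
                          (y(t) < 0 && alpha(t) < C - 1e-12);
      if (in_up && v > m_val) {
        m_val = v;
        i = t;
      }
      if (in_low && v < M_val) {
        M_val = v;
        j = t;
      }
    }
    if (i < 0 || j < 0 || m_val - M_val < tol) break;
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;  // indefinite kernel: bounded step
    double delta = (m_val - M_val) / eta;
    // clip so both multipliers stay in [0, C]
    delta = std::min(delta, y(i) > 0 ? C - alpha(i) : alpha(i));
    delta = std::min(delta, y(j) > 0 ? alpha(j) : C - alpha(j));
    if (delta <= 0) break;
    alpha(i) += y(i) * delta;
    alpha(j) -= y(j) * delta;
    f += delta * (K.col(i) - K.col(j));
    ++updates;
  }
  // bias: free support vectors if any, else midpoint of the active bounds
  double b = 0.0;
  uword nfree = 0;
  for (uword t = 0; t < N; ++t) {
    if (alpha(t) > 1e-8 && alpha(t) < C - 1e-8) {
      b += y(t) - f(t);
      ++nfree;
    }
  }
  b = nfree ? b / nfree
            : (std::isfinite(m_val) && std::isfinite(M_val)
                   ? 0.5 * (m_val + M_val)
                   : 0.0);
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("updates") = updates);
}
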