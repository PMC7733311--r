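#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-component terms of the bivariate normal log-density, precomputed
// once per iteration: log(pi_k) + const_k - q(x)/2 with q the Mahalanobis
// form from the closed 2x2 inverse.
struct Comp {
  double mx, my;        // mean
  double ia, ib, id;    // inverse covariance entries
  double lcst;          // log(weight) - log(2*pi) - log(det)/2
};

// One EM pass over preallocated buffers. Status: 0 ok, 1 underflow,
// 2 degenerate cluster, 3 singular covariance.
static int em_iterate(const mat& X, vec& w, mat& mu, cube& S, double eps,
                      double& loglik, mat& resp) {
  const uword N = X.n_rows, K = w.n_elem;
  std::vector<Comp> comp(K);
  for (uword k = 0; k < K; ++k) {
    const double a = S(0, 0, k), b = 0.5 * (S(0, 1, k) + S(1, 0, k)),
                 d = S(1, 1, k);
    const double det = a * d - b * b;
    if (!(det > 0.0) || !(a > 0.0)) return 3;
    comp[k] = {mu(k, 0), mu(k, 1), d / det, -b / det, a / det,
               std::log(w(k)) - std::log(2.0 * datum::pi) -
                   0.5 * std::log(det)};
  }
  const double* xs = X.colptr(0);
  const double* ys = X.colptr(1);
  double ll = 0.0;
  for (uword i = 0; i < N; ++i) {
    double mx = -datum::inf;
    for (uword k = 0; k < K; ++k) {
      const Comp& c = comp[k];
      const double dx = xs[i] - c.mx, dy = ys[i] - c.my;
      const double lp = c.lcst - 0.5 * (c.ia * dx * dx +
                                        2.0 * c.ib * dx * dy +
                                        c.id * dy * dy);
      resp(i, k) = lp;
      if (lp > mx) mx = lp;
    }
    if (!std::isfinite(mx)) return 1;
    double s = 0.0;
    for (uword k = 0; k < K; ++k) {
      const double e = std::exp(resp(i, k) - mx);
      resp(i, k) = e;
      s += e;
    }
    ll += mx + std::log(s);
    const double inv = 1.0 / s;
    for (uword k = 0; k < K; ++k) resp(i, k) *= inv;
  }
  loglik = ll;

  // M-step: accumulate weighted first and second moments per component
  for (uword k = 0; k < K; ++k) {
    const double* r = resp.colptr(k);
    double nk = 0.0, sx = 0.0, sy = 0.0;
    for (uword i = 0; i < N; ++i) {
      nk += r[i];
      sx += r[i] * xs[i];
      sy += r[i] * ys[i];
    }
    if (nk < 1e-12) return 2;
    const double mxk = sx / nk, myk = sy / nk;
    double sxx = 0.0, sxy = 0.0, syy = 0.0;
    for (uword i = 0; i < N; ++i) {
      const double dx = xs[i] - mxk, dy = ys[i] - myk;
      sxx += r[i] * dx * dx;
      sxy += r[i] * dx * dy;
      syy += r[i] * dy * dy;
    }
    w(k) = nk / double(N);
    mu(k, 0) = mxk;
    mu(k, 1) = myk;
    S(0, 0, k) = sxx / nk + eps;
    S(1, 1, k) = syy / nk + eps;
    S(0, 1, k) = S(1, 0, k) = sxy / nk;
  }
  return 0;
}

// log-likelihood of fixed parameters (no update)
static bool loglik_only(const mat& X, const vec& w, const mat& mu,
                        const cube& S, double& ll) {
  const uword N = X.n_rows, K = w.n_elem;
  std::vector<Comp> comp(K);
  for (uword k = 0; k < K; ++k) {
    const double a = S(0, 0, k), b = 0.5 * (S(0, 1, k) + S(1, 0, k)),
                 d = S(1, 1, k);
    const double det = a * d - b * b;
    if (!(det > 0.0) || !(a > 0.0)) return false;
    comp[k] = {mu(k, 0), mu(k, 1), d / det, -b / det, a / det,
               std::log(w(k)) - std::log(2.0 * datum::pi) -
                   0.5 * std::log(det)};
  }
  ll = 0.0;
  for (uword i = 0; i < N; ++i) {
    double mx = -datum::inf;
    double lp[64];
    for (uword k = 0; k < K; ++k) {
      const Comp& c = comp[k];
      const double dx = X(i, 0) - c.mx, dy = X(i, 1) - c.my;
      lp[k] = c.lcst - 0.5 * (c.ia * dx * dx + 2.0 * c.ib * dx * dy +
                              c.id * dy * dy);
      if (lp[k] > mx) mx = lp[k];
    }
    if (!std::isfinite(mx)) return false;
    double s = 0.0;
    for (uword k = 0; k < K; ++k) s += std::exp(lp[k] - mx);
    ll += mx + std::log(s);
  }
  return true;
}

// Full EM fit from a given initialization. Convergence on absolute
// log-likelihood change. The returned log-likelihood belongs to the
// RETURNED parameters (one extra E evaluation after the last M update).
// [[Rcpp::export]]
Rcpp::List gmm_em_cpp(const arma::mat& X, const arma::mat& mu0,
                      const arma::cube& S0, const arma::vec& w0,
                      double tol, int max_iter, double eps) {
  vec w = w0;
  mat mu = mu0;
  cube S = S0;
  if (w.n_elem > 64) Rcpp::stop("more than 64 components not supported");
  mat resp(X.n_rows, w.n_elem);
  double ll = -datum::inf, ll_prev = -datum::inf;
  bool converged = false;
  int status = 0, iter = 0;
  std::vector<double> trace;
  trace.reserve(64);
  for (iter = 0; iter < max_iter; ++iter) {
    double cur;
    status = em_iterate(X, w, mu, S, eps, cur, resp);
    if (status != 0) break;
    trace.push_back(cur);
    ll = cur;
    if (iter > 0 && std::abs(cur - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = cur;
  }
  double ll_final = ll;
  if (status == 0) {
    double v;
    if (loglik_only(X, w, mu, S, v)) ll_final = v;
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = w, Rcpp::Named("means") = mu,
      Rcpp::Named("covs") = S, Rcpp::Named("loglik") = ll_final,
      Rcpp::Named("ll_trace") = trace,
      Rcpp::Named("n_iter") = iter + (converged ? 1 : 0),
      Rcpp::Named("converged") = converged, Rcpp::Named("status") = status);
}

// Responsibilities + log-likelihood for fixed parameters (one E-step).
// [[Rcpp::export]]
Rcpp::List gmm_estep_cpp(const arma::mat& X, const arma::mat& mu,
                         const arma::cube& S, const arma::vec& w) {
  const uword N = X.n_rows, K = w.n_elem;
  mat lp(N, K);
  for (uword k = 0; k < K; ++k) {
    const double a = S(0, 0, k), b = 0.5 * (S(0, 1, k) + S(1, 0, k)),
                 d = S(1, 1, k);
    const double det = a * d - b * b;
    if (!(det > 0.0) || !(a > 0.0))
      Rcpp::stop("singular covariance in component %d", k + 1);
    const double ia = d / det, ib = -b / det, id = a / det;
    const double lcst = std::log(w(k)) - std::log(2.0 * datum::pi) -
                        0.5 * std::log(det);
    for (uword i = 0; i < N; ++i) {
      const double dx = X(i, 0) - mu(k, 0), dy = X(i, 1) - mu(k, 1);
      lp(i, k) = lcst - 0.5 * (ia * dx * dx + 2.0 * ib * dx * dy +
                               id * dy * dy);
    }
  }
  vec mx = max(lp, 1);
  for (uword i = 0; i < N; ++i)
    if (!std::isfinite(mx(i)))
      Rcpp::stop("density underflow for observation %d", i + 1);
  vec lse = mx + log(sum(exp(lp.each_col() - mx), 1));
  mat resp = exp(lp.each_col() - lse);
  return Rcpp::List::create(Rcpp::Named("resp") = resp,
                            Rcpp::Named("loglik") = accu(lse));
}
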