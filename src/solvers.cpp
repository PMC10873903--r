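#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Convolution-smoothed check loss with a Gaussian kernel.
// rho_{tau,h}(v) = (tau - 1/2) v + (1/2) E|v + h Z|,  Z ~ N(0,1)
//               = (tau - 1/2) v + (1/2) [ v (1 - 2 Phi(-v/h)) + 2 h phi(v/h) ]
// gradient  psi(v) = tau - Phi(-v/h);  curvature phi(v/h)/h <= 1/(h sqrt(2 pi)).

static inline double norm_pdf(double z) {
  return 0.3989422804014327 * std::exp(-0.5 * z * z);
}
static inline double norm_cdf(double z) {
  return 0.5 * std::erfc(-z * 0.7071067811865476);
}

static double smoothed_loss(const vec& r, double tau, double h) {
  double s = 0.0;
  const int n = r.n_elem;
  for (int i = 0; i < n; ++i) {
    double v = r[i], u = v / h;
    s += (tau - 0.5) * v + 0.5 * (v * (1.0 - 2.0 * norm_cdf(-u)) +
                                  2.0 * h * norm_pdf(u));
  }
  return s / n;
}

static void psi_vec(const vec& r, double tau, double h, vec& out) {
  const int n = r.n_elem;
  for (int i = 0; i < n; ++i) out[i] = tau - norm_cdf(-r[i] / h);
}

// Raw (unsmoothed) mean check loss, reported as the fit objective.
// [[Rcpp::export]]
double cpp_check_loss_mean(const arma::vec& r, double tau) {
  double s = 0.0;
  for (uword i = 0; i < r.n_elem; ++i)
    s += r[i] * (tau - (r[i] < 0 ? 1.0 : 0.0));
  return s / r.n_elem;
}

// Damped Newton on the smoothed check loss.  Returns coefficients,
// iteration count and convergence flag.
// [[Rcpp::export]]
Rcpp::List cpp_sqr_fit(const arma::mat& X, const arma::vec& y, double tau,
                       double h, double tol, int maxit,
                       const arma::vec& start) {
  const int n = X.n_rows, k = X.n_cols;
  vec b = start;
  vec r = y - X * b;
  vec psi(n), w(n);
  double obj = smoothed_loss(r, tau, h);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    psi_vec(r, tau, h, psi);
    for (int i = 0; i < n; ++i) w[i] = norm_pdf(r[i] / h) / h;
    vec g = X.t() * psi / n;                      // ascent direction sign
    mat H = X.t() * (X.each_col() % w) / n;
    H.diag() += 1e-10 + 1e-8 * trace(H) / k;
    vec d;
    if (!solve(d, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
      H.diag() += 1e-4;
      d = solve(H, g);
    }
    double step = 1.0, new_obj = 0.0;
    vec bn, rn;
    bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      bn = b + step * d;
      rn = y - X * bn;
      new_obj = smoothed_loss(rn, tau, h);
      if (new_obj <= obj + 1e-14 * std::abs(obj)) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) { converged = true; break; }        // no further descent
    double delta = max(abs(bn - b)) / std::max(1.0, max(abs(bn)));
    b = bn; r = rn; obj = new_obj;
    if (delta < tol) { converged = true; ++it; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = b,
      Rcpp::Named("residuals") = r,
      Rcpp::Named("smoothed_objective") = obj,
      Rcpp::Named("objective") = cpp_check_loss_mean(r, tau),
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}

// Marginal quantile fits for screening: for each mediator column m,
// fit y ~ [Xbase, m] and return the mediator coefficient.
// [[Rcpp::export]]
arma::vec cpp_marginal_qr(const arma::mat& Xbase, const arma::mat& M,
                          const arma::vec& y, double tau, double h,
                          double tol, int maxit) {
  const int p = M.n_cols, kb = Xbase.n_cols;
  vec out(p);
  mat X(Xbase.n_rows, kb + 1);
  X.cols(0, kb - 1) = Xbase;
  vec start0(kb + 1, fill::zeros);
  // warm start the shared part from the mediator-free fit (OLS-initialized)
  {
    vec s0 = solve(Xbase.t() * Xbase, Xbase.t() * y);
    Rcpp::List base = cpp_sqr_fit(Xbase, y, tau, h, tol, maxit, s0);
    vec bb = base["coefficients"];
    start0.subvec(0, kb - 1) = bb;
  }
  for (int j = 0; j < p; ++j) {
    X.col(kb) = M.col(j);
    Rcpp::List f = cpp_sqr_fit(X, y, tau, h, tol, maxit, start0);
    vec b = f["coefficients"];
    out[j] = b[kb];
  }
  return out;
}

// Scalar MCP proximal rule: argmin_t  w (z - t)^2 / 2 + pen_{lam,delta}(t).
// Requires delta * w > 1.
// [[Rcpp::export]]
double cpp_mcp_prox(double z, double w, double lam, double delta) {
  if (std::abs(z) >= delta * lam) return z;
  double thr = lam / w;
  double s = std::abs(z) - thr;
  if (s <= 0.0) return 0.0;
  double t = s / (1.0 - 1.0 / (delta * w));
  t = (z > 0 ? t : -t);
  // keep within the quadratic zone (numerical guard)
  if (std::abs(t) > delta * lam) t = (z > 0 ? delta * lam : -delta * lam);
  return t;
}

// MCP-penalized smoothed quantile regression along a lambda path.
// Majorize-minimize: quadratic upper bound with curvature c0 = 1/(h sqrt(2pi))
// per observation, inner coordinate descent with the scalar MCP rule.
// Only columns with penalize[j] == 1 are penalized.
// [[Rcpp::export]]
Rcpp::List cpp_mcp_path(const arma::mat& X, const arma::vec& y, double tau,
                        double h, const arma::vec& lambda, double delta,
                        const arma::uvec& penalize, double tol, int maxit,
                        const arma::vec& start) {
  const int n = X.n_rows, k = X.n_cols, nl = lambda.n_elem;
  const double c0 = 1.0 / (h * 2.5066282746310002);
  vec colss(k);
  for (int j = 0; j < k; ++j) colss[j] = dot(X.col(j), X.col(j));
  for (int j = 0; j < k; ++j) {
    if (penalize[j] && delta * c0 * colss[j] / n <= 1.0)
      Rcpp::stop("MCP concavity delta too small for the smoothing bandwidth (delta * weight <= 1)");
  }
  mat coefs(k, nl);
  vec objective(nl), smoothed(nl);
  ivec iters(nl);
  vec b = start;
  vec r = y - X * b;               // residual w.r.t. y
  vec psi(n);
  const mat XtX = X.t() * X;       // covariance-mode inner updates
  const double inner_tol = 1e-9;
  // one coordinate-descent pass; returns max absolute coefficient change
  auto cd_pass = [&](vec& b, vec& v, double lam, bool active_only) {
    double mx = 0.0;
    for (int j = 0; j < k; ++j) {
      if (active_only && penalize[j] && b[j] == 0.0) continue;
      double zj = b[j] + v[j] / colss[j];
      double bj_new;
      if (penalize[j]) {
        double wj = c0 * colss[j] / n;
        bj_new = cpp_mcp_prox(zj, wj, lam, delta);
      } else {
        bj_new = zj;
      }
      double diff = bj_new - b[j];
      if (diff != 0.0) {
        v -= XtX.col(j) * diff;
        b[j] = bj_new;
        double ad = std::abs(diff);
        if (ad > mx) mx = ad;
      }
    }
    return mx;
  };
  for (int l = 0; l < nl; ++l) {
    double lam = lambda[l];
    int it;
    for (it = 0; it < maxit; ++it) {
      psi_vec(r, tau, h, psi);
      // surrogate residual: res = ystar - X b = psi / c0; v = X' res
      vec v = X.t() * psi / c0;
      vec b_out = b;
      // inner CD on the quadratic surrogate: full pass, then active-set
      // passes to convergence, then a full pass to confirm
      for (int round = 0; round < 50; ++round) {
        double mx = cd_pass(b, v, lam, false);
        if (mx < inner_tol * std::max(1.0, max(abs(b)))) break;
        for (int sweep = 0; sweep < 50; ++sweep) {
          double mxa = cd_pass(b, v, lam, true);
          if (mxa < inner_tol * std::max(1.0, max(abs(b)))) break;
        }
      }
      r = y - X * b;
      double delta_b = max(abs(b - b_out)) / std::max(1.0, max(abs(b)));
      if (delta_b < tol) { ++it; break; }
    }
    coefs.col(l) = b;
    objective[l] = cpp_check_loss_mean(r, tau);
    smoothed[l] = smoothed_loss(r, tau, h);
    iters[l] = it;
  }
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = coefs,
      Rcpp::Named("objective") = objective,
      Rcpp::Named("smoothed_objective") = smoothed,
      Rcpp::Named("iterations") = iters);
}
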