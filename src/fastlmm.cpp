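// Profiled (RE)ML fitter for Gaussian linear mixed models with a single
// random intercept, specialised for channel-wise and permutation use where
// hundreds of thousands of refits are required.
//
// Model: y = X beta + Z u + e,  u ~ N(0, tau2 I_G),  e ~ N(0, sigma2 I_n),
// Z the participant indicator matrix. With lambda = tau2/sigma2 the marginal
// covariance is sigma2 * W, W = I + lambda Z Z'. Because Z is an indicator,
//   W^{-1} = I - Z diag(c_g) Z',   c_g = lambda / (1 + n_g lambda),
//   log|W|  = sum_g log(1 + n_g lambda),
// so all GLS quantities reduce to group sums and the profiled deviance is a
// smooth 1-D function of lambda, minimised by golden-section search on
// log(lambda) with an explicit lambda = 0 boundary check.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct Precomp {
  mat XtX;      // p x p
  vec Xty;      // p
  double yty;
  mat Sx;       // G x p group sums of X rows
  vec Sy;       // G   group sums of y
  vec ng;       // G   group sizes
  int n, p, G;
};

Precomp precompute(const mat& X, const vec& y, const ivec& g, int G) {
  Precomp pc;
  pc.n = X.n_rows; pc.p = X.n_cols; pc.G = G;
  pc.XtX = X.t() * X;
  pc.Xty = X.t() * y;
  pc.yty = dot(y, y);
  pc.Sx.zeros(G, pc.p);
  pc.Sy.zeros(G);
  pc.ng.zeros(G);
  for (int i = 0; i < pc.n; ++i) {
    int gi = g[i];
    pc.Sx.row(gi) += X.row(i);
    pc.Sy[gi] += y[i];
    pc.ng[gi] += 1.0;
  }
  return pc;
}

struct Eval {
  double crit;      // -2 log likelihood (REML or ML), profiled over sigma2
  double rss;       // W-weighted residual sum of squares
  double logdetW;
  double logdetA;
  vec beta;
  mat A;            // X' W^{-1} X
  bool ok;
};

Eval evaluate(const Precomp& pc, double lambda, bool reml) {
  Eval ev; ev.ok = false;
  mat A = pc.XtX;
  vec b = pc.Xty;
  double q = pc.yty;
  double logdetW = 0.0;
  if (lambda > 0) {
    for (int gi = 0; gi < pc.G; ++gi) {
      double ngg = pc.ng[gi];
      if (ngg <= 0) continue;
      double c = lambda / (1.0 + ngg * lambda);
      rowvec sx = pc.Sx.row(gi);
      A -= c * (sx.t() * sx);
      b -= c * pc.Sy[gi] * sx.t();
      q -= c * pc.Sy[gi] * pc.Sy[gi];
      logdetW += std::log1p(ngg * lambda);
    }
  }
  vec beta;
  bool solved = solve(beta, A, b, solve_opts::no_approx);
  if (!solved) return ev;
  double rss = q - dot(b, beta);
  if (rss <= 0) rss = std::numeric_limits<double>::min();
  double logdetA, signA;
  if (!log_det(logdetA, signA, A) || signA <= 0) return ev;
  const double LOG2PI = 1.8378770664093454836;
  double crit;
  int n = pc.n, p = pc.p;
  if (reml) {
    double s2 = rss / (n - p);
    crit = (n - p) * std::log(s2) + logdetW + logdetA +
           (n - p) + (n - p) * LOG2PI;
  } else {
    double s2 = rss / n;
    crit = n * std::log(s2) + logdetW + n + n * LOG2PI;
  }
  ev.crit = crit; ev.rss = rss; ev.logdetW = logdetW; ev.logdetA = logdetA;
  ev.beta = beta; ev.A = A; ev.ok = true;
  return ev;
}

// Golden-section minimisation of the profiled deviance over log(lambda).
double optimise_lambda(const Precomp& pc, bool reml, bool& ok) {
  const double lo = -18.0, hi = 13.0;
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  Eval e1 = evaluate(pc, std::exp(x1), reml);
  Eval e2 = evaluate(pc, std::exp(x2), reml);
  if (!e1.ok || !e2.ok) { ok = false; return 0.0; }
  double f1 = e1.crit, f2 = e2.crit;
  for (int it = 0; it < 80 && (b - a) > 1e-9; ++it) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      Eval e = evaluate(pc, std::exp(x1), reml);
      if (!e.ok) { ok = false; return 0.0; }
      f1 = e.crit;
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      Eval e = evaluate(pc, std::exp(x2), reml);
      if (!e.ok) { ok = false; return 0.0; }
      f2 = e.crit;
    }
  }
  double xin = 0.5 * (a + b);
  double lam = std::exp(xin);
  // boundary: a pure fixed-effects model may fit better than any lambda > 0
  Eval e0 = evaluate(pc, 0.0, reml);
  Eval ein = evaluate(pc, lam, reml);
  ok = ein.ok && e0.ok;
  if (!ok) return 0.0;
  return (e0.crit <= ein.crit) ? 0.0 : lam;
}

Rcpp::List fit_one(const Precomp& pc, bool reml) {
  bool ok = true;
  double lambda = optimise_lambda(pc, reml, ok);
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("converged") = false);
  }
  Eval ev = evaluate(pc, lambda, reml);
  int n = pc.n, p = pc.p;
  double s2 = reml ? ev.rss / (n - p) : ev.rss / n;
  mat Ainv;
  if (!inv_sympd(Ainv, symmatu(ev.A))) {
    if (!inv(Ainv, ev.A)) {
      return Rcpp::List::create(Rcpp::Named("converged") = false);
    }
  }
  vec se = sqrt(s2 * Ainv.diag());
  double loglik = -0.5 * ev.crit;
  return Rcpp::List::create(
    Rcpp::Named("beta") = ev.beta,
    Rcpp::Named("se") = se,
    Rcpp::Named("sigma2") = s2,
    Rcpp::Named("tau2") = lambda * s2,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("converged") = true);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".fastlmm_fit")]]
Rcpp::List fastlmm_fit(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& group, int n_groups, bool reml) {
  Precomp pc = precompute(X, y, group, n_groups);
  return fit_one(pc, reml);
}

// Channel-wise fits: for each column f_e of `feat`, fit
//   y ~ [Xbase, f_e]                     (modifier absent), or
//   y ~ [Xbase, f_e, f_e * modifier]     (interaction model),
// and return estimate, SE, Wald statistic and sign for the column of
// interest (the last one). REML throughout, matching coefficient reporting.
//' @noRd
// [[Rcpp::export(name = ".fastlmm_channelwise")]]
Rcpp::List fastlmm_channelwise(const arma::mat& Xbase, const arma::mat& feat,
                               const arma::vec& y, const arma::ivec& group,
                               int n_groups,
                               Rcpp::Nullable<Rcpp::NumericVector> modifier) {
  int E = feat.n_cols;
  int n = Xbase.n_rows;
  bool has_mod = modifier.isNotNull();
  vec modv;
  if (has_mod) modv = Rcpp::as<arma::vec>(modifier.get());
  int p = Xbase.n_cols + (has_mod ? 2 : 1);
  vec est(E), se(E), wald(E), lambda(E);
  ivec conv(E);
  mat X(n, p);
  X.cols(0, Xbase.n_cols - 1) = Xbase;
  for (int e = 0; e < E; ++e) {
    X.col(Xbase.n_cols) = feat.col(e);
    if (has_mod) X.col(Xbase.n_cols + 1) = feat.col(e) % modv;
    Precomp pc = precompute(X, y, group, n_groups);
    bool ok = true;
    double lam = optimise_lambda(pc, true, ok);
    if (!ok) { conv[e] = 0; est[e] = se[e] = wald[e] = lambda[e] = NA_REAL; continue; }
    Eval ev = evaluate(pc, lam, true);
    if (!ev.ok) { conv[e] = 0; est[e] = se[e] = wald[e] = lambda[e] = NA_REAL; continue; }
    double s2 = ev.rss / (n - p);
    mat Ainv;
    bool invok = inv_sympd(Ainv, symmatu(ev.A));
    if (!invok) invok = inv(Ainv, ev.A);
    if (!invok) { conv[e] = 0; est[e] = se[e] = wald[e] = lambda[e] = NA_REAL; continue; }
    int j = p - 1;
    double b = ev.beta[j];
    double s = std::sqrt(s2 * Ainv(j, j));
    est[e] = b; se[e] = s;
    wald[e] = (s > 0) ? (b / s) * (b / s) : NA_REAL;
    lambda[e] = lam;
    conv[e] = (s > 0) ? 1 : 0;
  }
  return Rcpp::List::create(
    Rcpp::Named("estimate") = est,
    Rcpp::Named("se") = se,
    Rcpp::Named("wald") = wald,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("converged") = conv);
}
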