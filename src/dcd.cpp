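#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for semi-quantitative SVR.
//
// Primal:  min  w'w + C1 * sum_binders xi1 + C2 * sum_nonbinders xi2
//   s.t.  |x_k.w - y_k| <= eps + xi1_k   (binders, shared slack)
//          x_k.w >= Ecut - xi2_k         (censored non-binders)
//          xi >= 0
//
// Dual variables gamma_k (one per record): binders gamma in [-C1, C1] with
// an eps * |gamma| term, non-binders gamma in [0, C2];  w = 0.5 * X'gamma
// with the sign convention gamma_binder = alpha_minus - alpha_plus.
// Each coordinate update is the exact 1-D maximiser (soft threshold, then
// clipping to the box), as in liblinear-style solvers.
//
// X is passed in CSR layout (row = record): xp (n+1), xi, xx.

// [[Rcpp::export]]
List dcd_semisvr(IntegerVector xp, IntegerVector xi, NumericVector xx,
                 int n_features, NumericVector y, LogicalVector censored,
                 double C1, double C2, double eps, double Ecut,
                 double tol, int max_pass, NumericVector gamma_init) {
  const int n = y.size();
  std::vector<double> w(n_features, 0.0);
  std::vector<double> gamma(n, 0.0);
  std::vector<double> kdiag(n, 0.0);

  for (int k = 0; k < n; ++k) {
    double s = 0.0;
    for (int t = xp[k]; t < xp[k + 1]; ++t) s += xx[t] * xx[t];
    kdiag[k] = s;
  }
  if (gamma_init.size() == n) {
    for (int k = 0; k < n; ++k) {
      if (kdiag[k] <= 0.0) continue;
      gamma[k] = gamma_init[k];
      for (int t = xp[k]; t < xp[k + 1]; ++t)
        w[xi[t]] += 0.5 * gamma[k] * xx[t];
    }
  }

  int pass = 0;
  bool converged = false;
  for (pass = 1; pass <= max_pass; ++pass) {
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const double kkk = kdiag[k];
      if (kkk <= 0.0) continue;
      double xw = 0.0;
      for (int t = xp[k]; t < xp[k + 1]; ++t) xw += xx[t] * w[xi[t]];
      const double target = censored[k] ? Ecut : y[k];
      const double b = target - (xw - 0.5 * gamma[k] * kkk);
      double g_new;
      if (censored[k]) {
        g_new = 2.0 * b / kkk;
        if (g_new < 0.0) g_new = 0.0;
        if (g_new > C2) g_new = C2;
      } else {
        double st = 0.0;
        if (b > eps) st = b - eps;
        else if (b < -eps) st = b + eps;
        g_new = 2.0 * st / kkk;
        if (g_new < -C1) g_new = -C1;
        if (g_new > C1) g_new = C1;
      }
      const double d = g_new - gamma[k];
      if (d != 0.0) {
        for (int t = xp[k]; t < xp[k + 1]; ++t) w[xi[t]] += 0.5 * d * xx[t];
        gamma[k] = g_new;
        const double viol = std::abs(d) * kkk;
        if (viol > max_viol) max_viol = viol;
      }
    }
    if (max_viol < tol) { converged = true; break; }
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["gamma"] = NumericVector(gamma.begin(), gamma.end()),
                      _["passes"] = pass, _["converged"] = converged);
}
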