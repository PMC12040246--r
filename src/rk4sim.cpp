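#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrator for the normalized-Hill logic network.
// Reactions are flattened: reaction j has operands
// opIdx[opStart[j] .. opStart[j]+opLen[j]-1] (0-based node indices) with
// inhibition flags in the same layout.  Time-varying reaction weights are
// tabulated on a uniform grid over [0, tMax] in wTab (nGrid x nReactions)
// and linearly interpolated; per-node dynamics are
// dy/dt = (ymax * OR_j(w_j * prod Hill) - y) / tau.

struct NetSpec {
  int nN, nR, nGrid;
  const double *ymax, *tau, *B, *Kn, *nHill, *wTab;
  const int *target, *opStart, *opLen, *opIdx, *inhib;
  double tMax;
};

static void rhs(const NetSpec &s, double t, const double *y, double *dydt,
                double *drive) {
  for (int i = 0; i < s.nN; ++i) drive[i] = 0.0;
  double pos = (s.nGrid - 1) * (t / s.tMax);
  if (pos < 0) pos = 0;
  if (pos > s.nGrid - 1) pos = s.nGrid - 1;
  int g0 = (int)pos;
  if (g0 > s.nGrid - 2) g0 = s.nGrid - 2;
  double frac = pos - g0;
  for (int j = 0; j < s.nR; ++j) {
    const double *col = s.wTab + (size_t)j * s.nGrid;
    double w = col[g0] + frac * (col[g0 + 1] - col[g0]);
    double a = w;
    int len = s.opLen[j];
    if (len > 0) {
      int st = s.opStart[j];
      for (int k = 0; k < len; ++k) {
        double x = y[s.opIdx[st + k]];
        if (x < 0) x = 0; else if (x > 1) x = 1;
        double nj = s.nHill[j];
        double xn = (nj == 1.0) ? x : (nj == 2.0 ? x * x : std::pow(x, nj));
        double f = s.B[j] * xn / (s.Kn[j] + xn);
        if (s.inhib[st + k]) f = 1.0 - f;
        a *= f;
      }
    }
    int ti = s.target[j];
    drive[ti] = drive[ti] + a - drive[ti] * a;
  }
  for (int i = 0; i < s.nN; ++i)
    dydt[i] = (s.ymax[i] * drive[i] - y[i]) / s.tau[i];
}

// [[Rcpp::export(name = ".rk4Simulate")]]
NumericMatrix rk4Simulate(NumericVector y0, NumericVector ymax,
                          NumericVector tau, IntegerVector target,
                          IntegerVector opStart, IntegerVector opLen,
                          IntegerVector opIdx, IntegerVector inhib,
                          NumericVector B, NumericVector Kn,
                          NumericVector nHill, NumericMatrix wTab,
                          double tMax, NumericVector times, double dt) {
  int nN = y0.size();
  NetSpec s;
  s.nN = nN; s.nR = target.size(); s.nGrid = wTab.nrow();
  s.ymax = REAL(ymax); s.tau = REAL(tau); s.B = REAL(B); s.Kn = REAL(Kn);
  s.nHill = REAL(nHill); s.wTab = REAL(wTab);
  s.target = INTEGER(target); s.opStart = INTEGER(opStart);
  s.opLen = INTEGER(opLen); s.opIdx = INTEGER(opIdx);
  s.inhib = INTEGER(inhib);
  s.tMax = tMax;

  int nT = times.size();
  NumericMatrix out(nT, nN);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(nN), k2(nN), k3(nN), k4(nN), tmp(nN), drv(nN);
  double t = times[0];
  for (int i = 0; i < nN; ++i) out(0, i) = y[i];
  for (int m = 1; m < nT; ++m) {
    double tEnd = times[m];
    while (t < tEnd - 1e-12) {
      double h = dt;
      if (t + h > tEnd) h = tEnd - t;
      rhs(s, t, y.data(), k1.data(), drv.data());
      for (int i = 0; i < nN; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
      rhs(s, t + 0.5 * h, tmp.data(), k2.data(), drv.data());
      for (int i = 0; i < nN; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
      rhs(s, t + 0.5 * h, tmp.data(), k3.data(), drv.data());
      for (int i = 0; i < nN; ++i) tmp[i] = y[i] + h * k3[i];
      rhs(s, t + h, tmp.data(), k4.data(), drv.data());
      for (int i = 0; i < nN; ++i) {
        y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        // guard against roundoff drift outside the admissible band
        if (y[i] < 0) y[i] = 0;
        else if (y[i] > s.ymax[i]) y[i] = s.ymax[i];
      }
      t += h;
    }
    for (int i = 0; i < nN; ++i) out(m, i) = y[i];
    t = tEnd;
  }
  return out;
}
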