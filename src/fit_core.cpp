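#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pinball (quantile) objective for a two-parameter conditional model.
// model = 0: f(x) = p0 + p1 * x              (linear quantile regression)
// model = 1: f(x) = exp(p0 + p1 * x)         (power law; x = log h, p0 = log C)
// Ties (y == f) contribute zero from either side, so the branch below is exact.
static double pinball(const double* x, const double* y, int n,
                      double p0, double p1, double tau, int model) {
  double loss = 0.0;
  if (model == 1) {
    for (int i = 0; i < n; ++i) {
      double r = y[i] - std::exp(p0 + p1 * x[i]);
      loss += (r >= 0.0) ? tau * r : (tau - 1.0) * r;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double r = y[i] - (p0 + p1 * x[i]);
      loss += (r >= 0.0) ? tau * r : (tau - 1.0) * r;
    }
  }
  return loss;
}

// [[Rcpp::export]]
double cpp_pinball(NumericVector x, NumericVector y,
                   double p0, double p1, double tau, int model) {
  return pinball(x.begin(), y.begin(), x.size(), p0, p1, tau, model);
}

// Nelder-Mead simplex search in two dimensions with standard coefficients
// (reflection 1, expansion 2, outside contraction 0.5, shrink 0.5).
// The pinball surface is piecewise linear in f, hence non-smooth; the
// simplex search is the standard derivative-free choice for it.
struct NMResult {
  double p0, p1, loss;
  int neval;
  bool converged;
};

static NMResult nelder_mead2(const double* x, const double* y, int n,
                             double tau, int model,
                             double s0, double s1,
                             double step0, double step1,
                             double tol, int maxit) {
  double P[3][2] = { {s0, s1},
                     {s0 + step0, s1},
                     {s0, s1 + step1} };
  double F[3];
  int neval = 0;
  for (int i = 0; i < 3; ++i) {
    F[i] = pinball(x, y, n, P[i][0], P[i][1], tau, model);
    ++neval;
  }
  bool converged = false;
  while (neval < maxit) {
    // order: lo, mid, hi
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (F[i] < F[lo]) lo = i;
      if (F[i] > F[hi]) hi = i;
    }
    int mid = 3 - lo - hi;
    if (lo == hi) { mid = 1; hi = 2; }  // all equal

    double frange = F[hi] - F[lo];
    double d0 = std::max(std::fabs(P[0][0] - P[lo][0]),
                         std::max(std::fabs(P[1][0] - P[lo][0]),
                                  std::fabs(P[2][0] - P[lo][0])));
    double d1 = std::max(std::fabs(P[0][1] - P[lo][1]),
                         std::max(std::fabs(P[1][1] - P[lo][1]),
                                  std::fabs(P[2][1] - P[lo][1])));
    if (frange <= tol * (std::fabs(F[lo]) + tol) &&
        d0 <= tol * (std::fabs(P[lo][0]) + tol) &&
        d1 <= tol * (std::fabs(P[lo][1]) + tol)) {
      converged = true;
      break;
    }

    double c0 = (P[lo][0] + P[mid][0]) * 0.5;  // centroid of the two best
    double c1 = (P[lo][1] + P[mid][1]) * 0.5;
    double r0 = c0 + (c0 - P[hi][0]);
    double r1 = c1 + (c1 - P[hi][1]);
    double fr = pinball(x, y, n, r0, r1, tau, model); ++neval;

    if (fr < F[lo]) {
      double e0 = c0 + 2.0 * (c0 - P[hi][0]);
      double e1 = c1 + 2.0 * (c1 - P[hi][1]);
      double fe = pinball(x, y, n, e0, e1, tau, model); ++neval;
      if (fe < fr) { P[hi][0] = e0; P[hi][1] = e1; F[hi] = fe; }
      else         { P[hi][0] = r0; P[hi][1] = r1; F[hi] = fr; }
    } else if (fr < F[mid]) {
      P[hi][0] = r0; P[hi][1] = r1; F[hi] = fr;
    } else {
      double cc0, cc1, fc;
      if (fr < F[hi]) {  // outside contraction
        cc0 = c0 + 0.5 * (c0 - P[hi][0]);
        cc1 = c1 + 0.5 * (c1 - P[hi][1]);
      } else {           // inside contraction
        cc0 = c0 - 0.5 * (c0 - P[hi][0]);
        cc1 = c1 - 0.5 * (c1 - P[hi][1]);
      }
      fc = pinball(x, y, n, cc0, cc1, tau, model); ++neval;
      if (fc < std::min(fr, F[hi])) {
        P[hi][0] = cc0; P[hi][1] = cc1; F[hi] = fc;
      } else {  // shrink towards the best vertex
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          P[i][0] = P[lo][0] + 0.5 * (P[i][0] - P[lo][0]);
          P[i][1] = P[lo][1] + 0.5 * (P[i][1] - P[lo][1]);
          F[i] = pinball(x, y, n, P[i][0], P[i][1], tau, model);
          ++neval;
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (F[i] < F[lo]) lo = i;
  NMResult res;
  res.p0 = P[lo][0]; res.p1 = P[lo][1]; res.loss = F[lo];
  res.neval = neval; res.converged = converged;
  return res;
}

// Multi-start driver. Starts from `init`; further starts perturb the best
// point so far by a deterministic, growing offset pattern. Stops early once
// an extra start fails to improve the best loss (relative 1e-9).
// [[Rcpp::export]]
List cpp_fit_pinball(NumericVector x, NumericVector y, double tau, int model,
                     NumericVector init, int max_starts,
                     double tol, int maxit) {
  const int n = x.size();
  const double off[4][2] = { {1.0, 1.0}, {-1.0, 1.0}, {1.0, -1.0}, {-1.0, -1.0} };
  double step0 = std::max(0.05, 0.05 * std::fabs(init[0]));
  double step1 = std::max(0.05, 0.05 * std::fabs(init[1]));

  NMResult best = nelder_mead2(x.begin(), y.begin(), n, tau, model,
                               init[0], init[1], step0, step1, tol, maxit);
  int starts = 1, neval = best.neval;
  bool all_converged = best.converged;
  while (starts < max_starts) {
    const double* o = off[(starts - 1) % 4];
    double scale = 0.1 * (1 + (starts - 1) / 4);
    NMResult r = nelder_mead2(x.begin(), y.begin(), n, tau, model,
                              best.p0 + o[0] * scale, best.p1 + o[1] * scale,
                              step0, step1, tol, maxit);
    ++starts; neval += r.neval;
    bool improved = r.loss < best.loss * (1.0 - 1e-9) - 1e-300;
    if (r.loss < best.loss) {
      all_converged = r.converged;
      best = r;
    }
    if (!improved) break;
  }
  return List::create(_["p0"] = best.p0, _["p1"] = best.p1,
                      _["loss"] = best.loss, _["neval"] = neval,
                      _["n_starts"] = starts,
                      _["converged"] = all_converged);
}
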