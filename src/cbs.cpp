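#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Circular binary segmentation core.
//
// An arc is the index set (i, j] (0-based, half-open) of a circularized
// sequence of length n; its complement is the remaining n - (j - i) points.
// The statistic is the two-sample t comparing arc mean vs complement mean
// with pooled variance. Wrap-around arcs are complements of linear arcs and
// give the same |t|, so scanning all linear (i, j) pairs covers the circle.
//
// With k = j - i, m = n - k, sa = arc sum, sc = total - sa:
//   d   = sa/k - sc/m
//   SS  = Qtot - sa^2/k - sc^2/m          (pooled within-group SS)
//   t^2 = d^2 (n-2) / (SS (1/k + 1/m))
// Per-width reciprocals are precomputed so the inner loop is division-free.

struct Widths {
  std::vector<double> invk, invm, coef;  // coef[k] = (n-2) / (1/k + 1/m)
};

static Widths make_widths(int n) {
  Widths w;
  w.invk.assign(n + 1, 0.0);
  w.invm.assign(n + 1, 0.0);
  w.coef.assign(n + 1, 0.0);
  for (int k = 1; k < n; ++k) {
    const double ik = 1.0 / k, im = 1.0 / (n - k);
    w.invk[k] = ik;
    w.invm[k] = im;
    w.coef[k] = (n - 2) / (ik + im);
  }
  return w;
}

struct ArcBest {
  int i, j;
  double t2;    // squared t statistic (1e300 sentinel when pooled var is 0)
  double sign;  // sign of (arc mean - complement mean)
};

// prefix sums S[k] = sum x[0..k-1]; Qtot = sum of squares
static double prefixes(const double *x, int n, std::vector<double> &S) {
  S[0] = 0.0;
  double q = 0.0;
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    q += x[k] * x[k];
  }
  return q;
}

// Scan all arcs with min_width <= width <= n - min_width, in (i, j) order.
// Ties are broken toward the earlier arc: a later arc must improve t^2 by a
// relative 1e-10 (the two complementary arcs of one split carry equal |t| up
// to rounding in the prefix sums).
static ArcBest scan_best(const std::vector<double> &S, double Qtot, int n,
                         int w, const Widths &wd) {
  const double T = S[n];
  ArcBest best = {0, std::min(w, n), -1.0, 0.0};
  for (int i = 0; i < n; ++i) {
    const int jlo = i + w, jhi = std::min(n, i + (n - w));
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i;
      const double sa = S[j] - S[i], sc = T - sa;
      const double d = sa * wd.invk[k] - sc * wd.invm[k];
      double SS = Qtot - sa * sa * wd.invk[k] - sc * sc * wd.invm[k];
      if (SS < 0) SS = 0;
      double t2;
      if (SS <= 0)
        t2 = (d == 0.0) ? 0.0 : 1e300;
      else
        t2 = d * d * wd.coef[k] / SS;
      if (t2 > best.t2 * (1.0 + 1e-10)) {
        best.i = i;
        best.j = j;
        best.t2 = t2;
        best.sign = (d >= 0) ? 1.0 : -1.0;
      }
    }
  }
  if (best.t2 < 0) best.t2 = 0;  // no admissible arc (n < 2w): degenerate
  return best;
}

// true iff some admissible arc reaches t^2 >= thresh; division-free
// (compares d^2 coef >= thresh * SS)
static bool scan_exceeds(const std::vector<double> &S, double Qtot, int n,
                         int w, const Widths &wd, double thresh) {
  const double T = S[n];
  for (int i = 0; i < n; ++i) {
    const int jlo = i + w, jhi = std::min(n, i + (n - w));
    if (jlo > jhi) continue;
    double sa = S[jlo] - S[i];
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i;
      const double sc = T - sa;
      const double d = sa * wd.invk[k] - sc * wd.invm[k];
      double SS = Qtot - sa * sa * wd.invk[k] - sc * sc * wd.invm[k];
      if (SS < 0) SS = 0;
      if (d * d * wd.coef[k] >= thresh * SS && d != 0.0) return true;
      if (j < n) sa += S[j + 1] - S[j];
    }
  }
  return false;
}

// [[Rcpp::export(name = ".cbs_scan_cpp")]]
List cbs_scan_cpp(NumericVector x, int min_width) {
  const int n = x.size();
  std::vector<double> S(n + 1);
  const double Qtot = prefixes(REAL(x), n, S);
  const Widths wd = make_widths(n);
  ArcBest b = scan_best(S, Qtot, n, min_width, wd);
  double t = (b.t2 >= 1e300) ? b.sign * 1e150 : b.sign * std::sqrt(b.t2);
  return List::create(_["i"] = b.i, _["j"] = b.j, _["t"] = t);
}

// Permutation test for the max-arc statistic. Uses R's RNG (Fisher-Yates via
// unif_rand) so results are reproducible from set.seed(). p = (b + 1)/(B + 1).
// With early_stop, permutation halts once b + 1 >= alpha * (B + 1): the full
// run's p-value would then be >= alpha with certainty, and the reported p,
// (b+1)/(done+1), is a valid conservative estimate for that decision.
// [[Rcpp::export(name = ".cbs_perm_cpp")]]
List cbs_perm_cpp(NumericVector x, int min_width, int n_perm, double alpha,
                  bool early_stop) {
  const int n = x.size();
  std::vector<double> S(n + 1);
  const double Qtot = prefixes(REAL(x), n, S);
  const Widths wd = make_widths(n);
  ArcBest obs = scan_best(S, Qtot, n, min_width, wd);
  const double t_obs =
      (obs.t2 >= 1e300) ? obs.sign * 1e150 : obs.sign * std::sqrt(obs.t2);

  if (obs.t2 <= 0.0) {  // flat input: nothing to test
    return List::create(_["i"] = obs.i, _["j"] = obs.j, _["t"] = 0.0,
                        _["p"] = 1.0, _["n_perm_used"] = 0, _["n_exceed"] = 0);
  }

  std::vector<double> y(REAL(x), REAL(x) + n);
  const double stop_at = alpha * (n_perm + 1);  // b+1 >= stop_at => p >= alpha
  int b = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int k = n - 1; k > 0; --k) {  // Fisher-Yates with R's RNG
      int r = static_cast<int>(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(y[k], y[r]);
    }
    const double q = prefixes(y.data(), n, S);
    if (scan_exceeds(S, q, n, min_width, wd, obs.t2)) ++b;
    ++done;
    if (early_stop && (b + 1) >= stop_at) break;
  }
  const double pval = (b + 1.0) / (done + 1.0);
  return List::create(_["i"] = obs.i, _["j"] = obs.j, _["t"] = t_obs,
                      _["p"] = pval, _["n_perm_used"] = done,
                      _["n_exceed"] = b);
}
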