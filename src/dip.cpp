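// Hartigan's dip statistic: the sup-norm distance from the empirical CDF to
// the closest unimodal CDF.  A unimodal CDF is convex left of its mode and
// concave right of it, with an atom permitted at the mode.  The optimum is
// attained with the mode at a data value, so we minimise over data-point
// modes; for each candidate mode the minimal feasible band half-width b is
// located by bisection over three monotone conditions:
//   (1) a convex CDF piece fits in the band [F-b, F+b] left of the mode,
//   (2) a concave piece fits right of the mode,
//   (3) the minimal attainable end value of the convex piece does not exceed
//       the maximal attainable start value of the concave piece (junction).
// Condition (3) is essential: without it the dip is underestimated whenever
// the mode candidate sits after a data gap that forces the left piece high.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ws {
  std::vector<double> vx, caps, lo, H;
  std::vector<int> hull;
};

// greatest convex minorant of (px[0..k), py[0..k)) with px strictly
// increasing, evaluated at the points themselves
void gcm_values(const std::vector<double>& px, const std::vector<double>& py,
                int k, std::vector<int>& hull, std::vector<double>& H) {
  hull.clear();
  for (int i = 0; i < k; ++i) {
    while ((int)hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull.back();
      if ((py[b] - py[a]) * (px[i] - px[b]) >= (py[i] - py[b]) * (px[b] - px[a]))
        hull.pop_back();
      else break;
    }
    hull.push_back(i);
  }
  H.resize(k);
  int seg = 0;
  for (int i = 0; i < k; ++i) {
    while (seg + 1 < (int)hull.size() && hull[seg + 1] < i) ++seg;
    if (i == hull[seg]) {
      H[i] = py[i];
    } else if (seg + 1 < (int)hull.size()) {
      int a = hull[seg], b = hull[seg + 1];
      if (i == b) H[i] = py[i];
      else H[i] = py[a] + (py[b] - py[a]) * (px[i] - px[a]) / (px[b] - px[a]);
    } else {
      H[i] = py[i];
    }
  }
}

// minimal end value (limit at v_end) of a convex nondecreasing sub-CDF with
// value caps `caps`, value floors `lo` at knots v[0..k); +Inf if infeasible
double vmin_convex(const std::vector<double>& v, const std::vector<double>& caps,
                   const std::vector<double>& lo, int k, double v_end, Ws& ws) {
  gcm_values(v, caps, k, ws.hull, ws.H);
  for (int i = 0; i < k; ++i)
    if (lo[i] - ws.H[i] > 1e-12) return R_PosInf;
  double vm = std::max(0.0, lo[k - 1]);
  for (int s = 0; s < k; ++s) {
    double sig = 0.0;
    for (int r = 0; r < s; ++r) {
      double cand = (lo[s] - ws.H[r]) / (v[s] - v[r]);
      if (cand > sig) sig = cand;
    }
    double val = lo[s] + sig * (v_end - v[s]);
    if (val > vm) vm = val;
  }
  return vm;
}

// feasibility of band half-width b with the mode at knot tau (0-based)
bool mode_feasible(int tau, double b, const std::vector<double>& v,
                   const std::vector<double>& F, const std::vector<double>& Fm,
                   int m, Ws& ws) {
  double vl = 0.0;
  if (tau > 0) {
    int k = tau + 1;
    ws.vx.resize(k); ws.caps.resize(k); ws.lo.resize(k);
    for (int i = 0; i < k; ++i) {
      ws.vx[i] = v[i];
      ws.caps[i] = Fm[i] + b;
      ws.lo[i] = (i < tau ? F[i] : Fm[i]) - b;
    }
    vl = vmin_convex(ws.vx, ws.caps, ws.lo, k, v[tau], ws);
    if (!R_FINITE(vl)) return false;
  }
  double vr = 1.0;
  if (tau < m - 1) {
    // mirror x -> -x, G -> 1 - G: the concave right piece becomes a convex
    // left piece; value caps come from the floors and vice versa
    int k = m - 1 - tau;
    ws.vx.resize(k); ws.caps.resize(k); ws.lo.resize(k);
    for (int j = 0; j < k; ++j) {
      int s = m - 1 - j;               // original knot, from m-1 down to tau+1
      ws.vx[j] = -v[s];
      ws.caps[j] = 1.0 - F[s] + b;
      ws.lo[j] = 1.0 - Fm[s] - b;
    }
    double vm = vmin_convex(ws.vx, ws.caps, ws.lo, k, -v[tau], ws);
    if (!R_FINITE(vm)) return false;
    vr = 1.0 - vm;
    if (vr > F[tau] + b) vr = F[tau] + b;
    if (vr < F[tau] - b - 1e-15) return false;  // own band violated at mode
  }
  return vl <= vr + 1e-15;
}

}  // namespace

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  int n = x.size();
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  std::vector<double> v;
  std::vector<int> cnt;
  for (int i = 0; i < n; ++i) {
    if (v.empty() || xs[i] != v.back()) { v.push_back(xs[i]); cnt.push_back(1); }
    else ++cnt.back();
  }
  int m = v.size();
  if (m == 1) return 0.0;
  std::vector<double> F(m), Fm(m);
  int acc = 0;
  for (int i = 0; i < m; ++i) {
    Fm[i] = (double)acc / n;
    acc += cnt[i];
    F[i] = (double)acc / n;
  }
  Ws ws;
  // cheap per-mode lower bound: half the larger of the two flank deviations
  // (empirical CDF above the cap hull on the left, below it on the right);
  // the junction condition can only raise the per-mode optimum above this
  std::vector<double> blb(m, 0.0);
  {
    std::vector<double> px(m), py(m), H;
    std::vector<int> hull;
    for (int tau = 0; tau < m; ++tau) {            // left flank
      int k = tau + 1;
      for (int i = 0; i < k; ++i) { px[i] = v[i]; py[i] = Fm[i]; }
      gcm_values(px, py, k, hull, H);
      double dev = 0.0;
      for (int i = 0; i < tau; ++i) dev = std::max(dev, F[i] - H[i]);
      dev = std::max(dev, Fm[tau] - H[tau]);
      blb[tau] = std::max(blb[tau], 0.5 * dev);
    }
    for (int tau = 0; tau < m; ++tau) {            // right flank, mirrored
      int k = m - tau;
      for (int j = 0; j < k; ++j) {
        int s = m - 1 - j;
        px[j] = -v[s]; py[j] = 1.0 - F[s];
      }
      gcm_values(px, py, k, hull, H);
      double dev = 0.0;
      for (int j = 0; j < k - 1; ++j) dev = std::max(dev, (1.0 - Fm[m - 1 - j]) - H[j]);
      blb[tau] = std::max(blb[tau], 0.5 * dev);
    }
  }
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return blb[a] < blb[b]; });
  double best = 0.5;
  for (int oi = 0; oi < m; ++oi) {
    int tau = order[oi];
    if (blb[tau] >= best - 1e-15) break;           // sorted: no mode can improve
    if (mode_feasible(tau, blb[tau], v, F, Fm, m, ws)) {
      best = blb[tau];                             // junction slack: bound is exact
      continue;
    }
    if (!mode_feasible(tau, best, v, F, Fm, m, ws)) continue;
    double lo = blb[tau], hi = best;
    for (int it = 0; it < 60 && hi - lo > 1e-14; ++it) {
      double mid = 0.5 * (lo + hi);
      if (mode_feasible(tau, mid, v, F, Fm, m, ws)) hi = mid; else lo = mid;
    }
    best = hi;
  }
  return best;
}
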