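#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hartigan's dip statistic: min over unimodal distribution functions G of
// sup |F_n - G|, where G is convex up to its mode, concave after it, with an
// atom permitted at the mode. For a candidate mode at the k-th distinct
// value, band feasibility within d of F_n decomposes into
//  - a convex band fit over the knots left of the mode (greatest convex
//    minorant of the upper band must clear the lower band),
//  - a mirrored concave band fit over the knots from the mode rightwards,
//    with the mode knot's upper bound relaxed to the post-atom value, and
//  - coupling terms: the minimal attainable left limit at the mode
//    (pair-extrapolation bounds through (upper_i, lower_j) box corners) must
//    not exceed the maximal attainable post-atom value (mirror bound).
// The dip is found by bisection on d.

struct PrefixInfo {
  // feas_all[j]: knots 0..j-1 convex-band feasible (feas_all[0] = true)
  // feas_exc[j]: as feas_all[j] but forgiving a box violation at knot j-1
  // extmin[k]:   minimal attainable extension value at x[k] of a feasible
  //              convex function over knots 0..k-1 (k >= 1); -inf if k == 0
  std::vector<char> feas_all, feas_exc;
  std::vector<double> extmin;
};

static PrefixInfo prefix_analysis(const std::vector<double>& x,
                                  const std::vector<double>& A,
                                  const std::vector<double>& B) {
  const double eps = 1e-12;
  int K = (int)x.size();
  PrefixInfo P;
  P.feas_all.assign(K + 1, 0);
  P.feas_exc.assign(K + 1, 0);
  P.extmin.assign(K + 1, -1e300);
  P.feas_all[0] = 1;
  P.feas_exc[0] = 1;

  // incremental lower hull of the upper-box points (x, B)
  std::vector<int> st;       // hull vertex indices
  bool alive = true;         // no interior violation so far
  for (int j = 0; j < K; ++j) {
    bool interior_viol = false;
    while ((int)st.size() >= 2) {
      int q = st[st.size() - 1], p = st[st.size() - 2];
      // keep q only if slope(p,q) < slope(q,j): a strictly convex turn
      double lhs = (B[j] - B[q]) * (x[q] - x[p]);
      double rhs = (B[q] - B[p]) * (x[j] - x[q]);
      if (lhs > rhs) break;
      st.pop_back();
    }
    if (!st.empty()) {
      int p = st.back();
      double slope = (B[j] - B[p]) / (x[j] - x[p]);
      for (int h = p + 1; h < j; ++h) {
        double val = B[p] + slope * (x[h] - x[p]);
        if (A[h] > val + eps) { interior_viol = true; break; }
      }
    }
    st.push_back(j);
    bool alive_before_endpoint = alive && !interior_viol;
    P.feas_exc[j + 1] = alive_before_endpoint ? 1 : 0;
    alive = alive_before_endpoint && (A[j] <= B[j] + eps);
    P.feas_all[j + 1] = alive ? 1 : 0;
  }

  // steepest required slope into each knot j from any earlier upper corner
  std::vector<double> S(K, -1e300);
  for (int j = 1; j < K; ++j) {
    double best = -1e300;
    for (int i = 0; i < j; ++i) {
      double s = (A[j] - B[i]) / (x[j] - x[i]);
      if (s > best) best = s;
    }
    S[j] = best;
  }
  for (int k = 1; k < K; ++k) {
    double e = A[k - 1];  // monotonicity floor
    for (int j = 1; j < k; ++j) {
      if (S[j] > 0) {
        double v = A[j] + S[j] * (x[k] - x[j]);
        if (v > e) e = v;
      }
    }
    P.extmin[k] = e;
  }
  return P;
}

static bool dip_feasible(double d,
                         const std::vector<double>& x,
                         const std::vector<double>& lo,
                         const std::vector<double>& up) {
  const double eps = 1e-12;
  int K = (int)x.size();
  std::vector<double> A(K), B(K);
  for (int i = 0; i < K; ++i) {
    A[i] = std::max(lo[i] - d, 0.0);
    B[i] = std::min(up[i] + d, 1.0);
  }
  PrefixInfo P = prefix_analysis(x, A, B);
  // reflected problem: concave fits become convex fits
  std::vector<double> xr(K), Ar(K), Br(K);
  for (int i = 0; i < K; ++i) {
    xr[i] = -x[K - 1 - i];
    Ar[i] = 1.0 - B[K - 1 - i];
    Br[i] = 1.0 - A[K - 1 - i];
  }
  PrefixInfo Pr = prefix_analysis(xr, Ar, Br);

  for (int k = 0; k < K; ++k) {
    if (!P.feas_all[k]) break;            // left prefixes only get harder
    int m = K - k;                        // reflected prefix length incl. mode
    if (!Pr.feas_exc[m]) continue;
    double Apt = std::max(lo[k] - d, 0.0);
    double Bpt = std::min(lo[k] + d, 1.0);
    double ellmin = (k >= 1) ? P.extmin[k] : -1e300;
    double rmax = (m >= 2) ? 1.0 - Pr.extmin[m - 1] : 1e300;
    if (rmax < Apt - eps) continue;
    double ell_cap = std::min(up[k] + d, 1.0);
    if (ellmin > ell_cap + eps) continue;
    if (ellmin > std::min(Bpt, rmax) + eps) continue;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".dip_stat_c")]]
double dip_stat_c(NumericVector vx, NumericVector cum) {
  int K = vx.size();
  if (K <= 1) return 0.0;
  std::vector<double> x(vx.begin(), vx.end());
  std::vector<double> lo(cum.begin(), cum.end());
  std::vector<double> up(K);
  up[0] = 0.0;
  for (int i = 1; i < K; ++i) up[i] = lo[i - 1];
  double loD = 0.0, hiD = 0.5;
  for (int it = 0; it < 40; ++it) {
    double mid = 0.5 * (loD + hiD);
    if (dip_feasible(mid, x, lo, up)) hiD = mid; else loD = mid;
  }
  return 0.5 * (loD + hiD);
}
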