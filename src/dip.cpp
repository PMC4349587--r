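// Hartigan's dip statistic: the minimal sup-norm distance between the
// empirical CDF and the class of unimodal CDFs (convex below the mode,
// concave above it, with at most one jump, at the mode).
//
// Computed by bisection on the distance epsilon. For a given epsilon the
// ECDF defines a tube [l_k, u_k] at each unique data value; a unimodal CDF
// within epsilon exists iff for some mode placement the left part admits a
// convex nondecreasing selection through the tubes and the right part a
// concave nondecreasing one, with the left endpoint not exceeding the right
// start (the jump at the mode). Convex-side feasibility is exact: the
// greatest convex minorant of the upper bounds must dominate the lower
// bounds; the endpoint extremes needed for the mode linkage follow from
// two-point slope certificates (a forced mean slope on [a,b] propagates by
// convexity). Mode placements between observations and at observations
// (where the ECDF jump can be absorbed by the mode's jump) are both
// enumerated.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

const double TOL = 1e-12;

// lower convex hull of (v, u) over the first s points must dominate l;
// if relax_last, l at the last prefix point is not enforced
bool convex_prefix_ok(const std::vector<double>& v,
                      const std::vector<double>& l,
                      const std::vector<double>& u,
                      int s, bool relax_last,
                      std::vector<int>& st) {
  st.clear();
  for (int k = 0; k < s; ++k) {
    while ((int)st.size() >= 2) {
      int b = st[st.size() - 1], a = st[st.size() - 2];
      // pop b when slope(a,b) >= slope(b,k)
      if ((u[b] - u[a]) * (v[k] - v[b]) >= (u[k] - u[b]) * (v[b] - v[a]))
        st.pop_back();
      else
        break;
    }
    st.push_back(k);
  }
  int seg = 0;
  for (int k = 0; k < s; ++k) {
    if (relax_last && k == s - 1) continue;
    while (seg + 1 < (int)st.size() && v[st[seg + 1]] < v[k]) ++seg;
    double hv;
    if (seg + 1 >= (int)st.size()) {
      hv = u[st.back()];
    } else {
      int a = st[seg], b = st[seg + 1];
      hv = (v[k] <= v[a]) ? u[a]
           : u[a] + (u[b] - u[a]) * (v[k] - v[a]) / (v[b] - v[a]);
    }
    if (hv < l[k] - TOL) return false;
  }
  return true;
}

// upper concave hull of (v, l) over points s..K-1 must stay below u;
// if relax_first, u at the first suffix point is not enforced
bool concave_suffix_ok(const std::vector<double>& v,
                       const std::vector<double>& l,
                       const std::vector<double>& u,
                       int s, int K, bool relax_first,
                       std::vector<int>& st) {
  st.clear();
  for (int k = s; k < K; ++k) {
    while ((int)st.size() >= 2) {
      int b = st[st.size() - 1], a = st[st.size() - 2];
      // pop b when slope(a,b) <= slope(b,k)
      if ((l[b] - l[a]) * (v[k] - v[b]) <= (l[k] - l[b]) * (v[b] - v[a]))
        st.pop_back();
      else
        break;
    }
    st.push_back(k);
  }
  int seg = 0;
  for (int k = s; k < K; ++k) {
    if (relax_first && k == s) continue;
    while (seg + 1 < (int)st.size() && v[st[seg + 1]] < v[k]) ++seg;
    double hv;
    if (seg + 1 >= (int)st.size()) {
      hv = l[st.back()];
    } else {
      int a = st[seg], b = st[seg + 1];
      hv = (v[k] <= v[a]) ? l[a]
           : l[a] + (l[b] - l[a]) * (v[k] - v[a]) / (v[b] - v[a]);
    }
    if (hv > u[k] + TOL) return false;
  }
  return true;
}

// v: unique sorted values (K of them); P: cumulative proportions, size K+1
bool unimodal_feasible(const std::vector<double>& v,
                       const std::vector<double>& P, double eps,
                       std::vector<double>& l, std::vector<double>& u,
                       std::vector<double>& sigma, std::vector<double>& tau,
                       std::vector<double>& cmin, std::vector<double>& dmax,
                       std::vector<int>& st) {
  int K = (int)v.size();
  l.resize(K); u.resize(K);
  for (int k = 0; k < K; ++k) {
    l[k] = std::max(0.0, P[k + 1] - eps);
    u[k] = std::min(1.0, P[k] + eps);
  }
  // forced-slope certificates
  sigma.assign(K, 0.0);
  tau.assign(K, 0.0);
  for (int b = 0; b < K; ++b)
    for (int a = 0; a < b; ++a) {
      double s = (l[b] - u[a]) / (v[b] - v[a]);
      if (s > sigma[b]) sigma[b] = s;
    }
  for (int b = 0; b < K; ++b)
    for (int c = b + 1; c < K; ++c) {
      double s = (l[c] - u[b]) / (v[c] - v[b]);
      if (s > tau[b]) tau[b] = s;
    }
  // cmin[s] = minimal feasible value of the convex side at its last point
  // (prefix of s points); dmax[s] = maximal feasible value of the concave
  // side at its first point (suffix starting at index s)
  cmin.assign(K + 1, 0.0);
  dmax.assign(K + 1, 1.0);
  for (int s = 1; s <= K; ++s) {
    double m = l[s - 1];
    for (int b = 0; b < s; ++b) {
      double cand = l[b] + sigma[b] * (v[s - 1] - v[b]);
      if (cand > m) m = cand;
    }
    cmin[s] = m;
  }
  for (int s = K - 1; s >= 0; --s) {
    double m = u[s];
    for (int b = s; b < K; ++b) {
      double cand = u[b] - tau[b] * (v[b] - v[s]);
      if (cand < m) m = cand;
    }
    dmax[s] = m;
  }
  // prefix/suffix feasibility (monotone: once infeasible, stays so)
  int smaxL = 0;
  for (int s = 1; s <= K; ++s) {
    if (!convex_prefix_ok(v, l, u, s, false, st)) break;
    smaxL = s;
  }
  int sminR = K;  // smallest suffix start with feasible suffix
  for (int s = K - 1; s >= 0; --s) {
    if (!concave_suffix_ok(v, l, u, s, K, false, st)) break;
    sminR = s;
  }
  // mode strictly between points (or outside the range): left prefix of s
  // points, right suffix starting at s
  for (int s = 0; s <= K; ++s) {
    if (s > smaxL) break;
    if (s < sminR && s < K) continue;
    if (s == 0 || s == K) return true;
    if (cmin[s] <= dmax[s] + TOL) return true;
  }
  // mode at observation k: the ECDF jump there can be matched by the mode's
  // jump; left tube at k relaxed to P[k] +/- eps, right to P[k+1] +/- eps
  for (int k = 0; k < K; ++k) {
    if (k > smaxL) break;                    // prefix of k points must fit
    if (k + 1 < sminR) continue;             // suffix from k+1 must fit
    if (!convex_prefix_ok(v, l, u, k + 1, true, st)) continue;
    if (!concave_suffix_ok(v, l, u, k, K, true, st)) continue;
    double lrel = std::max(0.0, P[k] - eps);
    double urel = std::min(1.0, P[k + 1] + eps);
    double cm = lrel;
    for (int b = 0; b < k; ++b) {
      double cand = l[b] + sigma[b] * (v[k] - v[b]);
      if (cand > cm) cm = cand;
    }
    double dm = urel;
    for (int b = k + 1; b < K; ++b) {
      double cand = u[b] - tau[b] * (v[b] - v[k]);
      if (cand < dm) dm = cand;
    }
    if (cm <= dm + TOL) return true;
  }
  return false;
}

double dip_sorted(const std::vector<double>& x) {
  int n = (int)x.size();
  if (n < 1) Rcpp::stop("empty sample");
  std::vector<double> v, P(1, 0.0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    v.push_back(x[i]);
    P.push_back((double)j / n);
    i = j;
  }
  double floorD = 0.5 / n;
  if ((int)v.size() == 1) return floorD;
  std::vector<double> l, u, sigma, tau, cmin, dmax;
  std::vector<int> st;
  double lo = 0.0, hi = 0.25;
  if (!unimodal_feasible(v, P, hi, l, u, sigma, tau, cmin, dmax, st))
    hi = 0.5;  // defensive; the dip never exceeds 1/4
  for (int it = 0; it < 40; ++it) {
    double mid = 0.5 * (lo + hi);
    if (unimodal_feasible(v, P, mid, l, u, sigma, tau, cmin, dmax, st))
      hi = mid;
    else
      lo = mid;
  }
  return std::max(hi, floorD);
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_sorted(xs);
}

// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int nboot) {
  NumericVector out(nboot);
  std::vector<double> xs(n);
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = R::unif_rand();
    std::sort(xs.begin(), xs.end());
    out[b] = dip_sorted(xs);
  }
  return out;
}
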