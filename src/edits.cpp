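#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

// Banded (Ukkonen) Levenshtein distance with cutoff: returns the exact
// distance if it is <= k, otherwise k + 1. Cells outside the diagonal band
// of half-width k cannot lie on a path of cost <= k.
static int bounded_lev(const std::string &a, const std::string &b, int k) {
  const int la = (int) a.size(), lb = (int) b.size();
  if (std::abs(la - lb) > k) return k + 1;
  const int INF = k + 1;
  std::vector<int> prev(lb + 2, INF), cur(lb + 2, INF);
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= k) ? j : INF;
  if (lb + 1 <= lb + 1) prev[lb + 1] = INF;
  for (int i = 1; i <= la; ++i) {
    const int lo = std::max(1, i - k), hi = std::min(lb, i + k);
    if (lo - 1 == 0) cur[0] = (i <= k) ? i : INF; else cur[lo - 1] = INF;
    int rowmin = cur[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      int v = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      if (del < v) v = del;
      if (ins < v) v = ins;
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (hi + 1 <= lb + 1) cur[hi + 1] = INF;
    if (rowmin >= INF) return INF;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], INF);
}

// Distances from one query to many targets, capped at k (k+1 = "exceeds k").
// [[Rcpp::export]]
IntegerVector bounded_edit_cpp(std::string query, CharacterVector targets,
                               int k) {
  const int n = targets.size();
  IntegerVector out(n);
  for (int t = 0; t < n; ++t)
    out[t] = bounded_lev(query, as<std::string>(targets[t]), k);
  return out;
}

// Nearest eligible centroid under the UNOISE skew rule: a centroid of size
// c is eligible at distance d iff s/c <= 2^-(alpha*d + 1) and 1 <= d <=
// max_dist; the nearest eligible centroid wins, distance ties go to the
// larger size. The band of each distance computation is capped both by the
// centroid's own eligibility radius and by the best distance found so far,
// which keeps the scan cheap once a close centroid is known. Returns the
// 1-based index or 0.
// [[Rcpp::export]]
int denoise_pick_cpp(std::string query, CharacterVector targets,
                     NumericVector sizes, double s, double alpha,
                     int max_dist) {
  int best = -1, best_d = max_dist + 1;
  double best_c = -1;
  const int lq = (int) query.size();
  for (int t = 0; t < targets.size(); ++t) {
    const double c = sizes[t];
    if (c < s) continue;                       // skew > 1/4 for any d >= 1
    int dmax = (int) std::floor((std::log2(c / s) - 1.0) / alpha + 1e-9);
    if (dmax < 1) continue;
    int cap = std::min(dmax, std::min(max_dist, best_d));
    std::string tg = as<std::string>(targets[t]);
    if (std::abs((int) tg.size() - lq) > cap) continue;
    const int d = bounded_lev(query, tg, cap);
    if (d < 1 || d > cap) continue;
    if (d < best_d || (d == best_d && c > best_c)) {
      best = t; best_d = d; best_c = c;
    }
  }
  return best + 1;
}

// Best-identity assignment for read mapping: identity = 1 - d / max(la,
// lb); the highest-identity target with identity >= min_identity wins,
// exact ties going to the earliest target (callers pass targets in
// abundance order). Identity comparisons use exact integer
// cross-multiplication; bands shrink as the best improves. Returns the
// 1-based index or 0.
// [[Rcpp::export]]
int map_pick_cpp(std::string query, CharacterVector targets,
                 double min_identity) {
  const int lq = (int) query.size();
  int best = -1;
  long best_d = 0, best_m = 1;                 // best identity = 1 - d/m
  for (int t = 0; t < targets.size(); ++t) {
    std::string tg = as<std::string>(targets[t]);
    const long m = std::max(lq, (int) tg.size());
    // threshold band: d <= (1 - min_identity) * m
    long cap = (long) std::floor((1.0 - min_identity) * m + 1e-9);
    if (best >= 0) {
      // must be strictly better: d/m < best_d/best_m
      const long improve = (best_d * m) / best_m -
        ((best_d * m) % best_m == 0 ? 1 : 0);
      cap = std::min(cap, improve);
    }
    if (cap < 0 || std::abs((int) tg.size() - lq) > cap) continue;
    const long d = bounded_lev(query, tg, (int) cap);
    if (d > cap) continue;
    if (best < 0 || d * best_m < best_d * m) {
      best = t; best_d = d; best_m = m;
    }
  }
  return best + 1;
}
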