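#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// counts * log(counts), with 0 log 0 = 0
static inline double clogc(double c) { return c > 0.0 ? c * std::log(c) : 0.0; }

// Order of indices by value, ties broken by index (deterministic).
static std::vector<int> sort_order(const NumericVector &v) {
  std::vector<int> idx(v.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// rank-equipartition bin assignment into nb bins (0-based)
static std::vector<int> equipartition(const NumericVector &v, int nb) {
  int n = v.size();
  std::vector<int> ord = sort_order(v);
  std::vector<int> bin(n);
  for (int r = 0; r < n; ++r) {
    int b = (int)(( (long long)r * nb) / n);
    if (b >= nb) b = nb - 1;
    bin[ord[r]] = b;
  }
  return bin;
}

// Maximal mutual information (nats) between a consecutive-group partition of
// the rows of `counts` (ncand x a, row-ordered by the y value) into b groups
// and the columns, for every b in 2..bmax. Dynamic program over row prefixes.
//
// With counts c: I = (A - Bt - Ct)/n + log n where A = sum c_{gj} log c_{gj},
// Bt = sum_g c_g log c_g, Ct = sum_j c_j log c_j. A - Bt is additive over row
// groups, Ct is fixed, so the DP maximizes sum over groups of
// score(group) = sum_j c_{gj} log c_{gj} - c_g log c_g.
static void max_mi_dp(const std::vector<double> &counts, int ncand, int a,
                      double n, int bmax, std::vector<double> &mi_out) {
  // prefix cumulative counts per column
  std::vector<double> cum((ncand + 1) * a, 0.0);
  for (int r = 0; r < ncand; ++r)
    for (int j = 0; j < a; ++j)
      cum[(r + 1) * a + j] = cum[r * a + j] + counts[r * a + j];

  double col_term = 0.0;  // sum_j c_j log c_j
  for (int j = 0; j < a; ++j) col_term += clogc(cum[ncand * a + j]);

  // score of merging rows (s, t]
  auto score = [&](int s, int t) {
    double tot = 0.0, val = 0.0;
    for (int j = 0; j < a; ++j) {
      double c = cum[t * a + j] - cum[s * a + j];
      val += clogc(c);
      tot += c;
    }
    return val - clogc(tot);
  };

  std::vector<double> Fprev(ncand + 1, -1e300), Fcur(ncand + 1, -1e300);
  for (int t = 1; t <= ncand; ++t) Fprev[t] = score(0, t);  // k = 1
  for (int k = 2; k <= bmax; ++k) {
    for (int t = k; t <= ncand; ++t) {
      double best = -1e300;
      for (int s = k - 1; s < t; ++s) {
        double v = Fprev[s] + score(s, t);
        if (v > best) best = v;
      }
      Fcur[t] = best;
    }
    // partitions into *at most* k groups: allow empty trailing merge by also
    // taking the k-1 value (a coarser partition is a valid b-grid too)
    double val = std::max(Fcur[ncand], Fprev[ncand]);
    mi_out[k] = (val - col_term) / n + std::log(n);
    std::swap(Fprev, Fcur);
    Fprev[ncand] = val;  // carry best-so-far for the "at most" semantics
  }
}

// One orientation: equipartition `u` into a columns, DP-optimize row cuts on
// `v`; returns the best normalized score found.
static double mic_orientation(const NumericVector &u, const NumericVector &v,
                              double B, int max_axis, int cand_factor) {
  int n = u.size();
  double best = 0.0;
  int amax = std::min((double)max_axis, B / 2.0);
  for (int a = 2; a <= amax; ++a) {
    int bmax = std::min((double)max_axis, std::floor((B - 1e-9) / a));
    if (bmax < 2) continue;
    std::vector<int> colbin = equipartition(u, a);
    int ncand = std::min(n, std::min(cand_factor * bmax, 60));
    if (ncand < bmax) ncand = std::min(n, bmax);
    std::vector<int> rowbin = equipartition(v, ncand);
    std::vector<double> counts(ncand * a, 0.0);
    for (int i = 0; i < n; ++i) counts[rowbin[i] * a + colbin[i]] += 1.0;
    std::vector<double> mi(bmax + 1, 0.0);
    max_mi_dp(counts, ncand, a, (double)n, bmax, mi);
    for (int b = 2; b <= bmax; ++b) {
      double norm = std::log((double)std::min(a, b));
      double val = mi[b] / norm;
      if (val > best) best = val;
    }
  }
  return best;
}

// [[Rcpp::export]]
double mic_cpp(NumericVector x, NumericVector y, double exponent,
               int max_axis, int cand_factor) {
  int n = x.size();
  double B = std::pow((double)n, exponent);
  double best = std::max(mic_orientation(x, y, B, max_axis, cand_factor),
                         mic_orientation(y, x, B, max_axis, cand_factor));
  if (best < 0.0) best = 0.0;
  if (best > 1.0) best = 1.0;
  return best;
}
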