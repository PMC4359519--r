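#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Signed max deviation between the set CDF and the complement CDF over
// rank positions. `p` holds the sorted 1-based rank positions of the m
// set genes among G ranks. The deviation D(i) = F(i) - B(i) can only
// increase at set positions and decrease elsewhere, so the maximum is
// attained at some p_j and the minimum just before some p_j (or at G,
// where D = 0). Ties between d+ and |d-| resolve to d+.
static double ks_signed(const int* p, int m, int G) {
  const double dm = (double)m, db = (double)(G - m);
  double dplus = 0.0, dminus = 0.0;
  for (int j = 1; j <= m; ++j) {
    const double gap = (double)(p[j - 1] - j) / db;
    const double at = j / dm - gap;       // D(p_j)
    const double before = (j - 1) / dm - gap; // D(p_j - 1)
    if (at > dplus) dplus = at;
    if (before < dminus) dminus = before;
  }
  return (dplus >= -dminus) ? dplus : dminus;
}

// Weighted flavor: CDFs accumulate |weight| mass instead of counts.
// `w` is the per-rank weight (rank order), `S` its prefix sum.
static double ks_signed_weighted(const int* p, int m,
                                 const double* w, const double* S, int G) {
  double wm = 0.0;
  for (int j = 0; j < m; ++j) wm += w[p[j] - 1];
  const double wtot = S[G - 1];
  const double wb = wtot - wm;
  if (wm <= 0.0 || wb <= 0.0) return 0.0;
  double dplus = 0.0, dminus = 0.0, acc = 0.0;
  for (int j = 0; j < m; ++j) {
    const int pj = p[j];
    const double before = acc / wm - ((pj > 1 ? S[pj - 2] : 0.0) - acc) / wb;
    acc += w[pj - 1];
    const double at = acc / wm - (S[pj - 1] - acc) / wb;
    if (at > dplus) dplus = at;
    if (before < dminus) dminus = before;
  }
  return (dplus >= -dminus) ? dplus : dminus;
}

// [[Rcpp::export(name = ".ks_stat_cpp")]]
double ks_stat_cpp(IntegerVector pos_sorted, int G) {
  return ks_signed(INTEGER(pos_sorted), pos_sorted.size(), G);
}

// [[Rcpp::export(name = ".ks_stat_weighted_cpp")]]
double ks_stat_weighted_cpp(IntegerVector pos_sorted, NumericVector w,
                            NumericVector S) {
  return ks_signed_weighted(INTEGER(pos_sorted), pos_sorted.size(),
                            REAL(w), REAL(S), w.size());
}

// Mean |statistic| over n_perm uniformly drawn size-m position sets.
// Uses R's RNG (caller seeds the stream); the candidate pool is kept
// across permutations by undoing each partial Fisher-Yates shuffle, so
// a draw costs O(m), not O(G). When `w`/`S` are non-empty the weighted
// statistic is used.
// [[Rcpp::export(name = ".perm_mean_abs_cpp")]]
double perm_mean_abs_cpp(int G, int m, int n_perm,
                         NumericVector w = NumericVector(0),
                         NumericVector S = NumericVector(0)) {
  if (m < 1 || m >= G) stop("set size must satisfy 1 <= m < G");
  if (n_perm < 1) stop("n_perm must be >= 1");
  const bool weighted = w.size() > 0;
  std::vector<int> pool(G);
  for (int i = 0; i < G; ++i) pool[i] = i + 1;
  std::vector<int> pos(m), picked(m);
  double acc = 0.0;
  for (int t = 0; t < n_perm; ++t) {
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (G - j));
      if (k >= G) k = G - 1;
      std::swap(pool[j], pool[k]);
      picked[j] = k;
      pos[j] = pool[j];
    }
    std::sort(pos.begin(), pos.end());
    acc += std::fabs(weighted
                       ? ks_signed_weighted(pos.data(), m, REAL(w), REAL(S), G)
                       : ks_signed(pos.data(), m, G));
    for (int j = m - 1; j >= 0; --j) std::swap(pool[j], pool[picked[j]]);
  }
  return acc / n_perm;
}
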