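#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Self-contained xorshift64* generator so forests are reproducible across
// platforms and independent of R's RNG state.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  int unif_int(int n) { return (int)(next() % (uint64_t) n); }
};

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left when x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // positive-class fraction at node
};

static void grow_node(const NumericMatrix &X, const IntegerVector &y,
                      std::vector<int> &idx, int lo, int hi, int depth,
                      int mtry, int min_split, int max_depth,
                      TreeNodes &T, int node, XRng &rng,
                      std::vector<int> &feat_pool) {
  const int n = hi - lo, p = X.ncol();
  int n_pos = 0;
  for (int r = lo; r < hi; ++r) n_pos += y[idx[r]];
  T.value[node] = (double) n_pos / n;
  T.feature[node] = -1;
  if (n < min_split || n_pos == 0 || n_pos == n || depth >= max_depth) return;

  // sample mtry distinct candidate features (partial Fisher-Yates)
  for (int f = 0; f < p; ++f) feat_pool[f] = f;
  int best_f = -1, best_cut_rank = -1;
  double best_gain = 0.0, best_thr = 0.0;
  const double parent_imp = 2.0 * ((double) n_pos / n) * (1.0 - (double) n_pos / n);
  std::vector<std::pair<double,int> > vals(n);
  for (int m = 0; m < mtry && m < p; ++m) {
    int pick = m + rng.unif_int(p - m);
    std::swap(feat_pool[m], feat_pool[pick]);
    int f = feat_pool[m];
    for (int r = 0; r < n; ++r) {
      int row = idx[lo + r];
      vals[r] = std::make_pair(X(row, f), y[row]);
    }
    std::sort(vals.begin(), vals.end());
    int lp = 0; // positives in left part
    for (int r = 0; r < n - 1; ++r) {
      lp += vals[r].second;
      if (vals[r].first == vals[r + 1].first) continue;
      int ln = r + 1, rn = n - ln, rp = n_pos - lp;
      double il = 2.0 * ((double) lp / ln) * (1.0 - (double) lp / ln);
      double ir = 2.0 * ((double) rp / rn) * (1.0 - (double) rp / rn);
      double gain = parent_imp - ((double) ln / n) * il - ((double) rn / n) * ir;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = vals[r].first + 0.5 * (vals[r + 1].first - vals[r].first);
        best_cut_rank = r;
      }
    }
  }
  if (best_f < 0) return; // no informative split among candidates

  // partition idx[lo..hi) in place (stable enough; order within halves is
  // irrelevant to the fitted tree)
  std::vector<int> lefts, rights;
  lefts.reserve(n); rights.reserve(n);
  for (int r = lo; r < hi; ++r) {
    if (X(idx[r], best_f) <= best_thr) lefts.push_back(idx[r]);
    else rights.push_back(idx[r]);
  }
  (void) best_cut_rank;
  if (lefts.empty() || rights.empty()) return; // degenerate (ties)
  for (size_t r = 0; r < lefts.size(); ++r) idx[lo + r] = lefts[r];
  for (size_t r = 0; r < rights.size(); ++r) idx[lo + lefts.size() + r] = rights[r];

  int nl = (int) T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0); T.left.push_back(-1);
  T.right.push_back(-1); T.value.push_back(0);
  int nr = (int) T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0); T.left.push_back(-1);
  T.right.push_back(-1); T.value.push_back(0);
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  T.left[node] = nl;
  T.right[node] = nr;
  int mid = lo + (int) lefts.size();
  grow_node(X, y, idx, lo, mid, depth + 1, mtry, min_split, max_depth, T, nl, rng, feat_pool);
  grow_node(X, y, idx, mid, hi, depth + 1, mtry, min_split, max_depth, T, nr, rng, feat_pool);
}

// Train a classification random forest (bootstrap aggregation of CART/gini
// trees with per-node random feature subsets). y must be 0/1.
// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                     int min_split, int max_depth, double seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y sizes differ");
  XRng rng((uint64_t) seed * 6364136223846793005ULL + 1442695040888963407ULL);
  List trees(ntree);
  std::vector<int> feat_pool(X.ncol());
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int r = 0; r < n; ++r) idx[r] = rng.unif_int(n); // bootstrap
    TreeNodes T;
    T.feature.push_back(-1); T.threshold.push_back(0); T.left.push_back(-1);
    T.right.push_back(-1); T.value.push_back(0);
    grow_node(X, y, idx, 0, n, 0, mtry, min_split, max_depth, T, 0, rng, feat_pool);
    int nn = (int) T.feature.size();
    NumericMatrix tm(nn, 5);
    for (int r = 0; r < nn; ++r) {
      tm(r, 0) = T.feature[r];
      tm(r, 1) = T.threshold[r];
      tm(r, 2) = T.left[r];
      tm(r, 3) = T.right[r];
      tm(r, 4) = T.value[r];
    }
    trees[t] = tm;
  }
  return trees;
}

// Score = fraction of trees whose leaf votes positive (leaf positive
// fraction >= 0.5), i.e. the vote fraction in [0, 1].
// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while ((int) tm(node, 0) >= 0) {
        int f = (int) tm(node, 0);
        node = (X(r, f) <= tm(node, 1)) ? (int) tm(node, 2) : (int) tm(node, 3);
      }
      if (tm(node, 4) >= 0.5) out[r] += 1.0;
    }
  }
  for (int r = 0; r < n; ++r) out[r] /= ntree;
  return out;
}
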