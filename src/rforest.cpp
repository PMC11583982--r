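#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal bagged regression forest (CART with variance-reduction splits,
// mtry random candidate features per node, bootstrap resampling, out-of-bag
// predictions). Self-contained because the deployment image carries no
// random-forest package; used by the ABC regression-adjustment step.

static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int rand_below(uint64_t& state, int n) {
  return (int)(splitmix64(state) % (uint64_t)n);
}

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  double value;     // leaf mean
};

struct Tree {
  std::vector<Node> nodes;
};

static int build_node(Tree& tree,
                      const NumericMatrix& X,
                      const NumericVector& y,
                      std::vector<int>& idx, int lo, int hi,
                      int mtry, int min_node, uint64_t& rng) {
  const int n_node = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int k = lo; k < hi; ++k) {
    sum += y[idx[k]];
    sum2 += y[idx[k]] * y[idx[k]];
  }
  const double mean = sum / n_node;
  const double sse = sum2 - sum * sum / n_node;

  const int me = (int)tree.nodes.size();
  tree.nodes.push_back({-1, 0.0, -1, -1, mean});
  if (n_node < 2 * min_node || sse <= 1e-12) return me;

  const int p = X.ncol();
  int best_f = -1;
  double best_thr = 0.0, best_gain = 0.0;
  std::vector<std::pair<double, double> > xy;
  xy.reserve(n_node);

  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    int r = j + rand_below(rng, p - j);
    std::swap(feats[j], feats[r]);
  }

  for (int j = 0; j < mtry && j < p; ++j) {
    const int f = feats[j];
    xy.clear();
    for (int k = lo; k < hi; ++k)
      xy.push_back(std::make_pair(X(idx[k], f), y[idx[k]]));
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double lsum = 0.0;
    for (int k = 0; k < n_node - 1; ++k) {
      lsum += xy[k].second;
      if (xy[k].first == xy[k + 1].first) continue;
      const int nl = k + 1, nr = n_node - nl;
      if (nl < min_node || nr < min_node) continue;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n_node;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xy[k].first + xy[k + 1].first);
      }
    }
  }
  if (best_f < 0) return me;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return me; // numeric ties; give up

  tree.nodes[me].feature = best_f;
  tree.nodes[me].threshold = best_thr;
  const int l = build_node(tree, X, y, idx, lo, mid, mtry, min_node, rng);
  tree.nodes[me].left = l;
  const int r = build_node(tree, X, y, idx, mid, hi, mtry, min_node, rng);
  tree.nodes[me].right = r;
  return me;
}

static double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.nodes[node].feature >= 0) {
    node = (X(row, tree.nodes[node].feature) <= tree.nodes[node].threshold)
               ? tree.nodes[node].left
               : tree.nodes[node].right;
  }
  return tree.nodes[node].value;
}

// Fit a forest of `ntree` trees to (X, y) and return:
//  - oob: out-of-bag prediction per training row (NaN if never out of bag)
//  - pred: prediction for each row of Xnew
// [[Rcpp::export(name = ".rf_regress_cpp")]]
List rf_regress_cpp(NumericMatrix X, NumericVector y, NumericMatrix Xnew,
                    int ntree, int mtry, int min_node, int seed) {
  const int n = X.nrow();
  uint64_t rng = ((uint64_t)(uint32_t)seed << 32) ^ 0xA0761D6478BD642FULL;
  splitmix64(rng);

  NumericVector oob_sum(n), pred_sum(Xnew.nrow());
  IntegerVector oob_cnt(n);
  std::vector<int> in_bag(n), idx;
  idx.reserve(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    idx.clear();
    for (int k = 0; k < n; ++k) {
      const int r = rand_below(rng, n);
      in_bag[r] += 1;
      idx.push_back(r);
    }
    Tree tree;
    tree.nodes.reserve(2 * n / min_node + 4);
    build_node(tree, X, y, idx, 0, n, mtry, min_node, rng);
    for (int i = 0; i < n; ++i) {
      if (!in_bag[i]) {
        oob_sum[i] += predict_tree(tree, X, i);
        oob_cnt[i] += 1;
      }
    }
    for (int i = 0; i < Xnew.nrow(); ++i)
      pred_sum[i] += predict_tree(tree, Xnew, i);
  }

  NumericVector oob(n);
  for (int i = 0; i < n; ++i)
    oob[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  NumericVector pred(Xnew.nrow());
  for (int i = 0; i < Xnew.nrow(); ++i) pred[i] = pred_sum[i] / ntree;

  return List::create(_["oob"] = oob, _["pred"] = pred);
}
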