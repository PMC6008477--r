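// Random forest classifier: CART trees with Gini splits, bootstrap
// resampling and per-node random feature subsets. Uses R's RNG so a
// set.seed() on the R side makes training deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left when x <= threshold
  int left, right;  // child node ids
  int pred;         // leaf class (0-based)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, min_node, max_depth;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_,
              int mtry_, int min_node_, int max_depth_)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_) {}

  int majority(const std::vector<int>& idx) const {
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (cnt[k] > cnt[best]) best = k; // tie -> lowest class index
    return best;
  }

  static double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double g = 1.0;
    for (size_t k = 0; k < cnt.size(); ++k) {
      double p = static_cast<double>(cnt[k]) / n;
      g -= p * p;
    }
    return g;
  }

  int build(std::vector<int>& idx, int depth, std::vector<int>& feat_pool) {
    int nn = static_cast<int>(idx.size());
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int nonzero = 0;
    for (int k = 0; k < K; ++k) nonzero += (cnt[k] > 0);

    bool leaf = nonzero <= 1 || nn < 2 * min_node || depth >= max_depth;
    int best_f = -1;
    double best_thr = 0.0, best_imp = R_PosInf;
    double parent_imp = gini(cnt, nn);

    if (!leaf) {
      int p = static_cast<int>(feat_pool.size());
      int m = std::min(mtry, p);
      // partial Fisher-Yates to draw m features without replacement
      for (int j = 0; j < m; ++j) {
        int pick = j + static_cast<int>(unif_rand() * (p - j));
        if (pick >= p) pick = p - 1;
        std::swap(feat_pool[j], feat_pool[pick]);
      }
      std::vector<std::pair<double, int>> vals(nn);
      for (int j = 0; j < m; ++j) {
        int f = feat_pool[j];
        for (int a = 0; a < nn; ++a)
          vals[a] = std::make_pair(X(idx[a], f), y[idx[a]]);
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        std::vector<int> lc(K, 0), rc(cnt);
        for (int a = 0; a < nn - 1; ++a) {
          lc[vals[a].second]++;
          rc[vals[a].second]--;
          if (vals[a].first == vals[a + 1].first) continue;
          int nl = a + 1, nr = nn - nl;
          if (nl < min_node || nr < min_node) continue;
          double imp = (nl * gini(lc, nl) + nr * gini(rc, nr)) / nn;
          if (imp < best_imp) {
            best_imp = imp;
            best_f = f;
            best_thr = 0.5 * (vals[a].first + vals[a + 1].first);
          }
        }
      }
      if (best_f < 0 || best_imp >= parent_imp - 1e-12) leaf = true;
    }

    int id = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    if (leaf) {
      nodes[id].feature = -1;
      nodes[id].pred = majority(idx);
      return id;
    }
    std::vector<int> left_idx, right_idx;
    left_idx.reserve(nn);
    right_idx.reserve(nn);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? left_idx : right_idx).push_back(i);
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].pred = -1;
    int l = build(left_idx, depth + 1, feat_pool);
    int r = build(right_idx, depth + 1, feat_pool);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  int predict_row(const NumericMatrix& Xt, int row) const {
    int id = 0;
    while (nodes[id].feature >= 0)
      id = (Xt(row, nodes[id].feature) <= nodes[id].threshold)
               ? nodes[id].left
               : nodes[id].right;
    return nodes[id].pred;
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_votes")]]
IntegerMatrix rf_votes(NumericMatrix X, IntegerVector y, int n_classes,
                       NumericMatrix Xtest, int ntree, int mtry,
                       int min_node, int max_depth) {
  int n = X.nrow();
  if (n != y.size()) stop("X and y sizes differ");
  if (Xtest.ncol() != X.ncol()) stop("train/test feature counts differ");
  IntegerMatrix votes(Xtest.nrow(), n_classes);
  GetRNGstate();
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) {
      int pick = static_cast<int>(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      boot[i] = pick;
    }
    TreeBuilder tb(X, y, n_classes, mtry, min_node, max_depth);
    std::vector<int> pool(X.ncol());
    for (int f = 0; f < X.ncol(); ++f) pool[f] = f;
    tb.build(boot, 0, pool);
    for (int r = 0; r < Xtest.nrow(); ++r) votes(r, tb.predict_row(Xtest, r))++;
  }
  PutRNGstate();
  return votes;
}
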