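// Compact random forest for binary classification: bagged CART trees with
// gini splits and per-node feature subsampling. Uses R's RNG so forests
// are reproducible under set.seed(). Probabilities are the forest average
// of leaf positive-class fractions; importance is the bootstrap-weighted
// mean decrease in gini impurity.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> leafp;     // positive fraction at leaf
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Partial Fisher-Yates: first m elements of a random permutation of 0..n-1
void sample_features(std::vector<int>& pool, int m) {
  int n = (int)pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + runif_int(n - i);
    std::swap(pool[i], pool[j]);
  }
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth, min_node;
  double n_train;
  Tree tree;
  std::vector<double>& importance;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int max_depth_, int min_node_, std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_), n_train(0.0), importance(imp) {
    feat_pool.resize(X.ncol());
    for (int f = 0; f < X.ncol(); ++f) feat_pool[f] = f;
  }

  int make_leaf(double n1, double n) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.leafp.push_back(n > 0 ? n1 / n : 0.0);
    return (int)tree.feature.size() - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    double n = (double)idx.size();
    double n1 = 0.0;
    for (int r : idx) n1 += y[r];
    bool pure = (n1 == 0.0 || n1 == n);
    if (pure || (max_depth > 0 && depth >= max_depth) ||
        (int)idx.size() < 2 * min_node)
      return make_leaf(n1, n);

    double parent_imp = gini(n1, n);
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    sample_features(feat_pool, mtry);

    std::vector<std::pair<double, int>> vals(idx.size());
    for (int fi = 0; fi < mtry; ++fi) {
      int f = feat_pool[fi];
      for (size_t k = 0; k < idx.size(); ++k)
        vals[k] = std::make_pair(X(idx[k], f), y[idx[k]]);
      std::sort(vals.begin(), vals.end());
      double ln = 0.0, l1 = 0.0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        ln += 1.0;
        l1 += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        double rn = n - ln, r1 = n1 - l1;
        if (ln < min_node || rn < min_node) continue;
        double gain = parent_imp -
          (ln / n) * gini(l1, ln) - (rn / n) * gini(r1, rn);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_f < 0) return make_leaf(n1, n);

    std::vector<int> li, ri;
    for (int r : idx)
      (X(r, best_f) <= best_thr ? li : ri).push_back(r);
    if (li.empty() || ri.empty()) return make_leaf(n1, n);

    importance[best_f] += (n / n_train) * best_gain;

    int node = make_leaf(n1, n); // placeholder, then overwrite as internal
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int lnode = build(li, depth + 1);
    int rnode = build(ri, depth + 1);
    tree.left[node] = lnode;
    tree.right[node] = rnode;
    return node;
  }
};

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int num_trees, int mtry,
                int max_depth, int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 rows");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::vector<double> importance(p, 0.0);
  List trees(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n); // bootstrap
    Builder b(X, y, mtry, max_depth, min_node, importance);
    b.n_train = (double)n;
    b.build(idx, 0);
    trees[t] = List::create(
      _["feature"] = wrap(b.tree.feature),
      _["threshold"] = wrap(b.tree.threshold),
      _["left"] = wrap(b.tree.left),
      _["right"] = wrap(b.tree.right),
      _["leafp"] = wrap(b.tree.leafp));
  }
  for (int f = 0; f < p; ++f) importance[f] /= (double)num_trees;
  return List::create(_["trees"] = trees, _["importance"] = wrap(importance));
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector leafp = tr["leafp"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += leafp[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= (double)T;
  return out;
}
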