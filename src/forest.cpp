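// Regression random forest: bootstrap CART with variance-reduction splits
// and mtry feature subsampling. Kept deliberately minimal — regression
// only, numeric features, no surrogate splits — but faithful to the
// standard algorithm (Breiman 2001): nodes are split exhaustively on the
// best of mtry randomly drawn features until they hold <= min_node
// samples or are pure; out-of-bag predictions are accumulated per tree.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;    // -1 for leaf
  double threshold;
  int left, right;
  double value;   // mean response (leaves)
};

struct TreeBuilder {
  const double* X;   // column-major n x p
  const double* y;
  int n_all, p;
  int mtry, min_node;
  std::mt19937_64& rng;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, double> > buf;  // (feature value, response)
  std::vector<Node> nodes;

  TreeBuilder(const double* X_, const double* y_, int n_, int p_, int mtry_,
              int min_node_, std::mt19937_64& rng_)
      : X(X_), y(y_), n_all(n_), p(p_), mtry(mtry_), min_node(min_node_),
        rng(rng_), feat_pool(p_), buf(n_) {}

  void build(std::vector<int>& idx, int lo, int hi, int node_id) {
    const int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) {
      const double yi = y[idx[i]];
      sum += yi;
      sum2 += yi * yi;
    }
    nodes[node_id].value = sum / n;
    nodes[node_id].feature = -1;
    if (n <= min_node) return;
    if (sum2 - sum * sum / n <= 1e-12) return;

    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    int best_feat = -1;
    double best_gain = 1e-12, best_thresh = 0.0;
    for (int t = 0; t < mtry; ++t) {
      std::uniform_int_distribution<int> pick(t, p - 1);
      std::swap(feat_pool[t], feat_pool[pick(rng)]);
      const int f = feat_pool[t];
      const double* col = X + (size_t)f * n_all;
      for (int i = 0; i < n; ++i) {
        const int r = idx[lo + i];
        buf[i].first = col[r];
        buf[i].second = y[r];
      }
      std::sort(buf.begin(), buf.begin() + n);
      double ls = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        ls += buf[i].second;
        if (buf[i + 1].first <= buf[i].first) continue;  // tie: no cut here
        const int nl = i + 1, nr = n - nl;
        const double rs = sum - ls;
        const double gain = ls * ls / nl + rs * rs / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thresh = 0.5 * (buf[i].first + buf[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return;

    const double* col = X + (size_t)best_feat * n_all;
    const double th = best_thresh;
    int* base = idx.data();
    int* mid_ptr = std::partition(base + lo, base + hi,
                                  [col, th](int r) { return col[r] <= th; });
    const int mid = (int)(mid_ptr - base);
    const int left_id = (int)nodes.size();
    nodes.push_back(Node());
    const int right_id = (int)nodes.size();
    nodes.push_back(Node());
    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thresh;
    nodes[node_id].left = left_id;
    nodes[node_id].right = right_id;
    build(idx, lo, mid, left_id);
    build(idx, mid, hi, right_id);
  }
};

static double predict_tree(const NumericMatrix& tree, const double* X,
                           int n, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = (int)tree(node, 0);
    node = (X[(size_t)f * n + row] <= tree(node, 1)) ? (int)tree(node, 2)
                                                     : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry must be in 1..ncol(X)");
  std::mt19937_64 rng((uint64_t)seed);
  List trees(ntree);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_n(n, 0);
  std::vector<int> idx(n);
  std::vector<char> inbag(n);
  std::uniform_int_distribution<int> boot(0, n - 1);
  const double* Xp = X.begin();

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      idx[i] = boot(rng);
      inbag[idx[i]] = 1;
    }
    TreeBuilder tb(Xp, y.begin(), n, p, mtry, min_node, rng);
    tb.nodes.resize(1);
    tb.build(idx, 0, n, 0);
    NumericMatrix tm((int)tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      tm(k, 0) = tb.nodes[k].feature;
      tm(k, 1) = tb.nodes[k].threshold;
      tm(k, 2) = tb.nodes[k].left;
      tm(k, 3) = tb.nodes[k].right;
      tm(k, 4) = tb.nodes[k].value;
    }
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_tree(tm, Xp, n, i);
        oob_n[i] += 1;
      }
    }
    trees[t] = tm;
  }
  NumericVector oob(n);
  for (int i = 0; i < n; ++i)
    oob[i] = oob_n[i] > 0 ? oob_sum[i] / oob_n[i] : NA_REAL;
  return List::create(_["trees"] = trees, _["oob"] = oob,
                      _["mtry"] = mtry, _["ntree"] = ntree,
                      _["min_node"] = min_node);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  const double* Xp = X.begin();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tm, Xp, n, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
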