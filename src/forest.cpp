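// Random-forest regression: bootstrap-aggregated CART trees with per-split
// feature subsampling (mtry). Self-contained RNG (mt19937) so fits are
// reproducible from an integer seed independently of R's RNG stream.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct TreeNode {
  int feat;      // -1 for leaf
  double thr;
  int left, right;
  double value;  // node mean (prediction if leaf)
};

struct Grower {
  const NumericMatrix& X;
  const std::vector<double>& y;
  int mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<TreeNode> nodes;

  Grower(const NumericMatrix& X_, const std::vector<double>& y_, int mtry_,
         int min_node_, int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(rng_) {}

  int grow(std::vector<int>& idx, int depth) {
    const int n = (int)idx.size();
    double sum = 0.0, ss = 0.0;
    for (int i : idx) { sum += y[i]; ss += y[i] * y[i]; }
    const double mean = sum / n;
    const double sse = ss - sum * sum / n;

    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, mean});

    if (n < 2 * min_node || depth >= max_depth || sse <= 1e-12 * (1.0 + ss))
      return me;

    // candidate features: mtry distinct columns
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feats[j], feats[pick(rng)]);
    }

    int best_feat = -1;
    double best_score = sum * sum / n;  // score of no split
    double best_thr = 0.0;

    std::vector<int> ord(idx);
    for (int f = 0; f < mtry && f < p; ++f) {
      const int j = feats[f];
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return X(a, j) < X(b, j); });
      double sl = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        sl += y[ord[k]];
        const int nl = k + 1, nr = n - nl;
        if (nl < min_node) continue;
        if (nr < min_node) break;
        if (X(ord[k], j) >= X(ord[k + 1], j)) continue;  // tied values
        const double sr = sum - sl;
        const double score = sl * sl / nl + sr * sr / nr;
        if (score > best_score + 1e-10) {
          best_score = score;
          best_feat = j;
          best_thr = 0.5 * (X(ord[k], j) + X(ord[k + 1], j));
        }
      }
    }
    if (best_feat < 0) return me;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_node || (int)ri.size() < min_node) return me;

    nodes[me].feat = best_feat;
    nodes[me].thr = best_thr;
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

NumericMatrix pack(const std::vector<TreeNode>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feat;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int j = (int)tree(node, 0);
    node = (X(row, j) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y sizes differ");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(ntree);
  std::vector<double> yy(y.begin(), y.end());
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Grower g(X, yy, mtry, min_node, max_depth, rng);
    g.grow(idx, 0);
    trees[t] = pack(g.nodes);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int t = 0; t < B; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  return out / (double)B;
}
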