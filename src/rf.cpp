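// Minimal CART regression random forest: bootstrap resampling, mtry feature
// subsampling, variance-reduction splits, impurity-decrease importance.
// Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;          // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;         // parent SSE minus children SSE
};

// best variance-reduction split over one feature for the samples in idx
void best_split_feature(const NumericMatrix& x, const NumericVector& y,
                        const std::vector<int>& idx, int feat,
                        double parent_sse, SplitResult& best) {
  const int n = idx.size();
  std::vector<std::pair<double, double>> v(n);  // (x value, y value)
  for (int i = 0; i < n; ++i)
    v[i] = {x(idx[i], feat), y[idx[i]]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return;  // constant within node
  double total = 0.0, total2 = 0.0;
  for (auto& p : v) { total += p.second; total2 += p.second * p.second; }
  double left_sum = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    left_sum += v[i].second;
    if (v[i].first == v[i + 1].first) continue;   // can't cut between equals
    const int nl = i + 1, nr = n - nl;
    const double right_sum = total - left_sum;
    // children SSE = total2 - sum_L^2/n_L - sum_R^2/n_R
    const double child_sse =
        total2 - left_sum * left_sum / nl - right_sum * right_sum / nr;
    const double gain = parent_sse - child_sse;
    if (gain > best.gain) {
      best.gain = gain;
      best.feature = feat;
      best.threshold = 0.5 * (v[i].first + v[i + 1].first);
    }
  }
}

double node_sse(const NumericVector& y, const std::vector<int>& idx,
                double& mean_out) {
  double s = 0.0, s2 = 0.0;
  for (int i : idx) { s += y[i]; s2 += y[i] * y[i]; }
  mean_out = s / idx.size();
  return s2 - s * s / idx.size();
}

int grow(std::vector<Node>& tree, const NumericMatrix& x,
         const NumericVector& y, std::vector<int>& idx, int mtry,
         int min_node, std::vector<double>& importance) {
  const int p = x.ncol();
  Node node;
  double mean;
  const double sse = node_sse(y, idx, mean);
  node.value = mean;
  const int self = tree.size();
  tree.push_back(node);
  if ((int)idx.size() < 2 * min_node || sse <= 0.0) return self;
  // sample mtry features without replacement (partial Fisher-Yates, R RNG)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  SplitResult best;
  for (int k = 0; k < mtry; ++k) {
    int r = k + (int)(unif_rand() * (p - k));
    if (r >= p) r = p - 1;
    std::swap(feats[k], feats[r]);
    best_split_feature(x, y, idx, feats[k], sse, best);
  }
  if (best.feature < 0) return self;
  std::vector<int> left_idx, right_idx;
  for (int i : idx) {
    if (x(i, best.feature) <= best.threshold) left_idx.push_back(i);
    else right_idx.push_back(i);
  }
  if (left_idx.empty() || right_idx.empty()) return self;
  importance[best.feature] += best.gain;
  tree[self].feature = best.feature;
  tree[self].threshold = best.threshold;
  tree[self].left = grow(tree, x, y, left_idx, mtry, min_node, importance);
  tree[self].right = grow(tree, x, y, right_idx, mtry, min_node, importance);
  return self;
}

double predict_one(const std::vector<Node>& tree, const NumericMatrix& x,
                   int row) {
  int cur = 0;
  while (tree[cur].feature >= 0)
    cur = (x(row, tree[cur].feature) <= tree[cur].threshold) ? tree[cur].left
                                                             : tree[cur].right;
  return tree[cur].value;
}

}  // namespace

// [[Rcpp::export(name = ".rf_forest_cpp")]]
List rf_forest_cpp(NumericMatrix x, NumericVector y, int ntree, int mtry,
                   int min_node, Nullable<NumericMatrix> xtest) {
  const int n = x.nrow(), p = x.ncol();
  if (y.size() != n) stop("x and y sizes differ");
  if (mtry < 1 || mtry > p) stop("invalid mtry");
  RNGScope scope;
  std::vector<double> importance(p, 0.0);
  NumericMatrix xt;
  bool has_test = xtest.isNotNull();
  NumericVector pred;
  if (has_test) {
    xt = NumericMatrix(xtest);
    pred = NumericVector(xt.nrow());
  }
  std::vector<int> boot(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      boot[i] = (r >= n) ? n - 1 : r;
    }
    std::vector<Node> tree;
    tree.reserve(2 * n);
    std::vector<int> idx(boot);
    grow(tree, x, y, idx, mtry, min_node, importance);
    if (has_test)
      for (int i = 0; i < xt.nrow(); ++i) pred[i] += predict_one(tree, xt, i);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  List out = List::create(Named("importance") = imp);
  if (has_test) {
    for (int i = 0; i < pred.size(); ++i) pred[i] /= ntree;
    out["predictions"] = pred;
  }
  return out;
}
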