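#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimal CART random forest for binary classification: bootstrap
// resampling, mtry random candidate features per node, Gini impurity,
// grown to purity (nodesize 1). Probabilities are the mean over trees
// of the terminal node's in-bag positive-class fraction; importance is
// the Gini decrease summed over a feature's splits, weighted by node
// size. Uses R's RNG throughout so results are seed-reproducible.

struct Node {
  int feature = -1;      // -1 = leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;     // leaf positive fraction
};

static double gini(int n1, int n) {
  if (n == 0) return 0.0;
  const double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry;
  std::vector<Node> nodes;
  std::vector<double>& importance;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, int>> buf;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), importance(imp) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx) {
    const int n = idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    Node nd;
    nd.prob = (double)n1 / n;
    const double imp_parent = gini(n1, n);
    if (n < 2 || n1 == 0 || n1 == n) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // draw mtry candidate features (partial Fisher-Yates, undone after)
    const int p = X.ncol();
    const int k = std::min(mtry, p);
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    for (int j = 0; j < k; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(feat_pool[j], feat_pool[r]);
      const int f = feat_pool[j];
      buf.clear();
      for (int i : idx) buf.push_back({X(i, f), y[i]});
      std::sort(buf.begin(), buf.end());
      int ln = 0, ln1 = 0;
      for (int t = 0; t + 1 < n; ++t) {
        ++ln;
        ln1 += buf[t].second;
        if (buf[t].first == buf[t + 1].first) continue;
        const int rn = n - ln, rn1 = n1 - ln1;
        const double gain = imp_parent -
          ((double)ln / n) * gini(ln1, ln) - ((double)rn / n) * gini(rn1, rn);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = (buf[t].first + buf[t + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) { // no impurity-reducing split
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    importance[best_f] += best_gain * n;
    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    nd.feature = best_f;
    nd.threshold = best_thr;
    nodes.push_back(nd);
    const int me = (int)nodes.size() - 1;
    const int l = build(li);
    const int r = build(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

static double predict_one(const std::vector<Node>& nodes, int root,
                          const NumericMatrix& X, int row) {
  int cur = root;
  while (nodes[cur].feature >= 0)
    cur = (X(row, nodes[cur].feature) <= nodes[cur].threshold)
            ? nodes[cur].left : nodes[cur].right;
  return nodes[cur].prob;
}

// [[Rcpp::export(name = ".rf_fit_predict_cpp")]]
List rf_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                        NumericMatrix Xte, int ntree, int mtry) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  if (ytr.size() != n) stop("label/feature length mismatch");
  if (ntree < 1) stop("ntree must be >= 1");
  std::vector<double> importance(p, 0.0), prob(nte, 0.0);
  std::vector<int> boot;
  for (int t = 0; t < ntree; ++t) {
    boot.clear();
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      boot.push_back(k);
    }
    TreeBuilder tb(Xtr, ytr, mtry, importance);
    const int root = tb.build(boot);
    for (int i = 0; i < nte; ++i) prob[i] += predict_one(tb.nodes, root, Xte, i);
  }
  NumericVector out(nte), imp(p);
  for (int i = 0; i < nte; ++i) out[i] = prob[i] / ntree;
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["prob"] = out, _["importance"] = imp);
}
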