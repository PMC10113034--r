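#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Seeded CART random forest (classification): bootstrap bagging, Gini
// splits on mtry random features, trees grown to purity (min node 1),
// mean-decrease-in-impurity importance. Deliberately self-contained so the
// whole phenotyping protocol is reproducible bit-for-bit from one seed.

namespace {

struct Rng { // xorshift64*
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Node {
  int feat = -1;          // -1 => leaf
  double thr = 0;
  int left = -1, right = -1;
  int pred = 0;
};

struct Tree {
  std::vector<Node> nodes;
};

double gini(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) { double p = (double)c / n; g -= p * p; }
  return g;
}

void grow(const NumericMatrix& X, const IntegerVector& y, int K,
          std::vector<int>& idx, int lo, int hi, Tree& tree, int nodeId,
          int mtry, Rng& rng, std::vector<double>& importance) {
  int n = hi - lo, p = X.ncol();
  std::vector<int> cnt(K, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int maj = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[maj]) maj = k;
  tree.nodes[nodeId].pred = maj;
  double g0 = gini(cnt, n);
  if (n < 2 || g0 <= 0) return;

  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) std::swap(feats[j], feats[j + rng.below(p - j)]);

  double bestGain = 0; int bestF = -1; double bestThr = 0;
  std::vector<std::pair<double, int>> vals(n);
  for (int fj = 0; fj < mtry; ++fj) {
    int f = feats[fj];
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    std::vector<int> lc(K, 0), rc(cnt);
    for (int i = 0; i + 1 < n; ++i) {
      lc[vals[i].second]++; rc[vals[i].second]--;
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      double gain = g0 - (nl * gini(lc, nl) + nr * gini(rc, nr)) / n;
      if (gain > bestGain + 1e-12) {
        bestGain = gain; bestF = f;
        bestThr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (bestF < 0) return;
  importance[bestF] += bestGain * n;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], bestF) <= bestThr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return; // numeric degeneracy

  Node& nd = tree.nodes[nodeId];
  nd.feat = bestF; nd.thr = bestThr;
  nd.left = tree.nodes.size(); tree.nodes.push_back(Node());
  grow(X, y, K, idx, lo, mid, tree, nd.left, mtry, rng, importance);
  int rightId = tree.nodes.size(); tree.nodes.push_back(Node());
  tree.nodes[nodeId].right = rightId;
  grow(X, y, K, idx, mid, hi, tree, rightId, mtry, rng, importance);
}

int predict1(const Tree& t, const NumericMatrix& X, int row) {
  int id = 0;
  while (t.nodes[id].feat >= 0)
    id = X(row, t.nodes[id].feat) <= t.nodes[id].thr ? t.nodes[id].left
                                                     : t.nodes[id].right;
  return t.nodes[id].pred;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
List rf_fit_predict(const NumericMatrix& Xtrain, const IntegerVector& ytrain,
                    const NumericMatrix& Xtest, int nclass, int ntree,
                    int mtry, double seed) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xtest.nrow();
  Rng rng((uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  IntegerMatrix votes(m, nclass);
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n); // bootstrap
    Tree tree; tree.nodes.push_back(Node());
    grow(Xtrain, ytrain, nclass, idx, 0, n, tree, 0, mtry, rng, importance);
    for (int j = 0; j < m; ++j) votes(j, predict1(tree, Xtest, j))++;
  }
  IntegerVector pred(m);
  for (int j = 0; j < m; ++j) {
    int best = 0;
    for (int k = 1; k < nclass; ++k) if (votes(j, k) > votes(j, best)) best = k;
    pred[j] = best;
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["pred"] = pred, _["votes"] = votes, _["importance"] = imp);
}
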