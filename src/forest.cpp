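// Random forest for binary classification with deterministic split
// rules: split candidates are midpoints between consecutive sorted
// distinct values; ties in the best split go to the lowest feature
// index, then the lowest threshold (guaranteed by ascending scan
// order and strict improvement). Per-feature importance is the sum of
// node-proportion-weighted Gini decreases at nodes split on the
// feature, accumulated per tree; mean decrease Gini is that sum
// divided by the number of trees. Uses R's RNG, so results are
// bit-reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeCtx {
  const NumericMatrix &x;
  const IntegerVector &y;
  const NumericMatrix &xtest;
  int p, mtry, min_node_size, n_root;
  std::vector<double> imp;        // per-tree importance, length p
  double leaf_gini;               // node-proportion-weighted leaf impurity
  IntegerMatrix &oob_votes;
  IntegerMatrix &test_votes;
};

inline double gini(int c0, int c1) {
  double m = c0 + c1;
  if (m <= 0.0) return 0.0;
  double p0 = c0 / m, p1 = c1 / m;
  return 1.0 - p0 * p0 - p1 * p1;
}

void sample_features(int p, int mtry, std::vector<int> &pool, std::vector<int> &out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  std::sort(out.begin(), out.end());
}

void grow(TreeCtx &ctx, std::vector<int> &idx, std::vector<int> &oob,
          std::vector<int> &test) {
  int m = idx.size();
  int c1 = 0;
  for (int i : idx) c1 += ctx.y[i];
  int c0 = m - c1;
  double g = gini(c0, c1);

  bool leaf = (c0 == 0 || c1 == 0 || m <= ctx.min_node_size);
  int best_f = -1;
  double best_dec = 0.0, best_thr = 0.0;

  if (!leaf) {
    static thread_local std::vector<int> pool;
    pool.resize(ctx.p);
    std::vector<int> feats;
    sample_features(ctx.p, ctx.mtry, pool, feats);
    std::vector<std::pair<double, int>> vals(m);
    for (int f : feats) {
      for (int i = 0; i < m; ++i)
        vals[i] = std::make_pair(ctx.x(idx[i], f), ctx.y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 1; i < m; ++i) {
        l1 += vals[i - 1].second;
        if (vals[i].first <= vals[i - 1].first) continue;
        int nl = i, nr = m - i;
        int r1 = c1 - l1;
        double dec = g - (double)nl / m * gini(nl - l1, l1)
                       - (double)nr / m * gini(nr - r1, r1);
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_f = f;
          best_thr = (vals[i - 1].first + vals[i].first) / 2.0;
        }
      }
    }
    if (best_f < 0 || best_dec <= 0.0) leaf = true;
  }

  if (leaf) {
    int pred = (c1 > c0) ? 1 : 0;              // tie -> class 0
    for (int i : oob) ctx.oob_votes(i, pred)++;
    for (int i : test) ctx.test_votes(i, pred)++;
    ctx.leaf_gini += (double)m / ctx.n_root * g;
    return;
  }

  ctx.imp[best_f] += (double)m / ctx.n_root * best_dec;

  std::vector<int> idx_l, idx_r, oob_l, oob_r, test_l, test_r;
  for (int i : idx) (ctx.x(i, best_f) <= best_thr ? idx_l : idx_r).push_back(i);
  for (int i : oob) (ctx.x(i, best_f) <= best_thr ? oob_l : oob_r).push_back(i);
  for (int i : test) (ctx.xtest(i, best_f) <= best_thr ? test_l : test_r).push_back(i);
  grow(ctx, idx_l, oob_l, test_l);
  grow(ctx, idx_r, oob_r, test_r);
}

} // namespace

// [[Rcpp::export(name = ".forest_cpp")]]
List forest_cpp(NumericMatrix x, IntegerVector y, NumericMatrix xtest,
                int ntree, int mtry, int min_node_size, bool per_tree) {
  int n = x.nrow(), p = x.ncol(), ntest = xtest.nrow();
  IntegerMatrix oob_votes(n, 2), test_votes(ntest, 2);
  NumericVector importance(p);
  NumericMatrix tree_imp(per_tree ? p : 1, per_tree ? ntree : 1);
  NumericVector root_gini(ntree), leaf_gini(ntree);

  std::vector<char> inbag(n);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
      inbag[j] = 1;
    }
    std::vector<int> oob, test(ntest);
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    for (int i = 0; i < ntest; ++i) test[i] = i;

    TreeCtx ctx{x, y, xtest, p, mtry, min_node_size, n,
                std::vector<double>(p, 0.0), 0.0, oob_votes, test_votes};
    int c1 = 0;
    for (int i : idx) c1 += y[i];
    root_gini[t] = gini(n - c1, c1);
    grow(ctx, idx, oob, test);
    leaf_gini[t] = ctx.leaf_gini;
    for (int f = 0; f < p; ++f) {
      importance[f] += ctx.imp[f];
      if (per_tree) tree_imp(f, t) = ctx.imp[f];
    }
  }
  for (int f = 0; f < p; ++f) importance[f] /= ntree;

  return List::create(_["mdg"] = importance,
                      _["per_tree"] = tree_imp,
                      _["root_gini"] = root_gini,
                      _["leaf_gini"] = leaf_gini,
                      _["oob_votes"] = oob_votes,
                      _["test_votes"] = test_votes);
}
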