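// Random forest for binary classification: bagged CART trees with Gini
// splitting and per-node random feature subsets; each tree casts a
// majority vote and the forest score is the fraction of trees voting
// the positive class. A self-contained xorshift RNG keeps training
// byte-reproducible for a given seed across platforms, independent of
// R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) {
    // splitmix64 scrambling so nearby seeds give unrelated streams
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    return s = x;
  }
  // uniform integer in [0, n); modulo bias is immaterial here (n << 2^64)
  int unif_int(int n) { return static_cast<int>(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feature;     // -1 marks a leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<double> vote;     // leaf majority vote (1 = positive class)
};

struct Builder {
  const NumericMatrix &x;
  const IntegerVector &y;
  int mtry, min_leaf;
  Xorshift &rng;
  Tree tree;
  std::vector<int> pool;                 // feature pool for sampling
  std::vector<std::pair<double, int> > buf;

  Builder(const NumericMatrix &x_, const IntegerVector &y_, int mtry_,
          int min_leaf_, Xorshift &rng_)
      : x(x_), y(y_), mtry(mtry_), min_leaf(min_leaf_), rng(rng_) {
    pool.resize(x.ncol());
    for (int j = 0; j < x.ncol(); ++j) pool[j] = j;
  }

  int new_node() {
    tree.feature.push_back(-1);
    tree.thresh.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.vote.push_back(0.0);
    return (int)tree.feature.size() - 1;
  }

  // Grow the subtree on idx[lo, hi); returns the node id.
  int grow(std::vector<int> &idx, int lo, int hi) {
    int n = hi - lo, npos = 0;
    for (int i = lo; i < hi; ++i) npos += y[idx[i]];
    int node = new_node();
    if (npos == 0 || npos == n || n < 2 * min_leaf || n < 2) {
      tree.vote[node] = (2 * npos >= n) ? 1.0 : 0.0;  // tie -> alarm
      return node;
    }
    double n_d = (double)n, pos_d = (double)npos;
    double parent = pos_d * (n_d - pos_d) / n_d;  // n * gini / 2
    int best_f = -1;
    double best_gain = 1e-12, best_t = 0.0;
    for (int m = 0; m < mtry; ++m) {
      int j = m + rng.unif_int((int)pool.size() - m);
      std::swap(pool[m], pool[j]);
      int f = pool[m];
      buf.clear();
      for (int i = lo; i < hi; ++i)
        buf.push_back(std::make_pair(x(idx[i], f), idx[i]));
      std::sort(buf.begin(), buf.end());
      int pos_l = 0;
      for (int kk = 1; kk < n; ++kk) {
        pos_l += y[buf[kk - 1].second];
        if (buf[kk].first <= buf[kk - 1].first) continue;  // tied values
        if (kk < min_leaf || n - kk < min_leaf) continue;
        double nl = (double)kk, nr = n_d - nl;
        double pl = (double)pos_l, prr = pos_d - pl;
        double child = pl * (nl - pl) / nl + prr * (nr - prr) / nr;
        double gain = parent - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_t = 0.5 * (buf[kk - 1].first + buf[kk].first);
        }
      }
    }
    if (best_f < 0) {  // all sampled features constant on this node
      tree.vote[node] = (2 * npos >= n) ? 1.0 : 0.0;
      return node;
    }
    int mid = (int)(std::partition(idx.begin() + lo, idx.begin() + hi,
                                   [&](int i) { return x(i, best_f) <= best_t; }) -
                    idx.begin());
    tree.feature[node] = best_f;
    tree.thresh[node] = best_t;
    int l = grow(idx, lo, mid);
    int r = grow(idx, mid, hi);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

double tree_vote(const IntegerVector &feature, const NumericVector &thresh,
                 const IntegerVector &left, const IntegerVector &right,
                 const NumericVector &vote, const NumericMatrix &x, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (x(row, feature[node]) <= thresh[node]) ? left[node] : right[node];
  return vote[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_build(NumericMatrix x, IntegerVector y, int n_trees, int mtry,
              int min_leaf, double seed) {
  int n = x.nrow();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1 || mtry > x.ncol()) stop("mtry out of range");
  Xorshift rng((uint64_t)seed);
  List forest(n_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);  // bootstrap
    Builder b(x, y, mtry, min_leaf, rng);
    b.grow(idx, 0, n);
    forest[t] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(), b.tree.feature.end()),
        _["thresh"] = NumericVector(b.tree.thresh.begin(), b.tree.thresh.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["vote"] = NumericVector(b.tree.vote.begin(), b.tree.vote.end()));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_score(List forest, NumericMatrix x) {
  int n = x.nrow(), nt = forest.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector thresh = tr["thresh"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector vote = tr["vote"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_vote(feature, thresh, left, right, vote, x, i);
  }
  return out / (double)nt;
}
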