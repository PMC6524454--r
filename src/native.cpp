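// Compiled helpers: a CART-based random forest (no forest package is
// available to link against) and a skip-gram negative-sampling word
// embedding trainer. Both use a private xorshift RNG so results are fully
// deterministic for a given seed and independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13U;
    s ^= s >> 7U;
    s ^= s << 17U;
    return s;
  }
  double unif() { return (double)(next() >> 11U) / 9007199254740992.0; }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;    // leaf positive fraction
};

double gini(int pos, int n) {
  if (n == 0) return 0.0;
  double p = (double)pos / n;
  return 2.0 * p * (1.0 - p);
}

int build_node(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
               int depth, XorShift& rng) {
  int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back((double)pos / n);
  if (pos == 0 || pos == n || n < min_node || depth >= 32) return node;

  int p = X.ncol();
  double parent = gini(pos, n);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_t = 0.0;

  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    int k = j + rng.below(p - j);
    std::swap(feats[j], feats[k]);
  }

  std::vector<std::pair<double, int> > vals(n);
  for (int m = 0; m < mtry && m < p; ++m) {
    int f = feats[m];
    for (int i = 0; i < n; ++i) {
      vals[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    }
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      int ln = i + 1, rn = n - ln;
      double g = parent - ((double)ln / n) * gini(lpos, ln)
                        - ((double)rn / n) * gini(pos - lpos, rn);
      if (g > best_gain) {
        best_gain = g;
        best_f = f;
        best_t = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_t) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return node;

  tree.feature[node] = best_f;
  tree.threshold[node] = best_t;
  int l = build_node(tree, X, y, idx, lo, mid, mtry, min_node, depth + 1, rng);
  int r = build_node(tree, X, y, idx, mid, hi, mtry, min_node, depth + 1, rng);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed) {
  int n = X.nrow();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n); // bootstrap sample
    Tree tree;
    build_node(tree, X, y, idx, 0, n, mtry, min_node, 0, rng);
    trees[t] = List::create(
      Named("feature") = wrap(tree.feature),
      Named("threshold") = wrap(tree.threshold),
      Named("left") = wrap(tree.left),
      Named("right") = wrap(tree.right),
      Named("value") = wrap(tree.value));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  int ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// Skip-gram with negative sampling. `corpus` holds 0-based token ids with
// -1 marking sentence boundaries (windows never cross them). Returns the
// input (center-word) vectors.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(IntegerVector corpus, int vocab_size, int d,
                             int window, int negative, int epochs,
                             double lr, int seed) {
  XorShift rng((uint64_t)seed * 1099511628211ULL + 3ULL);
  std::vector<double> W((size_t)vocab_size * d);
  std::vector<double> C((size_t)vocab_size * d, 0.0);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (rng.unif() - 0.5) / d;

  // unigram^0.75 negative-sampling table
  std::vector<double> freq(vocab_size, 0.0);
  int total = 0;
  for (int i = 0; i < corpus.size(); ++i) {
    if (corpus[i] >= 0) { freq[corpus[i]] += 1.0; ++total; }
  }
  const int TABLE = 100000;
  std::vector<int> table(TABLE);
  double z = 0.0;
  for (int v = 0; v < vocab_size; ++v) z += std::pow(freq[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(freq[0], 0.75) / z;
    for (int i = 0; i < TABLE; ++i) {
      table[i] = v;
      if ((double)(i + 1) / TABLE > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(freq[v], 0.75) / z;
      }
    }
  }

  std::vector<double> grad(d);
  long long steps_total = (long long)epochs * total;
  long long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < corpus.size(); ++i) {
      int center = corpus[i];
      if (center < 0) continue;
      double alpha = lr * std::max(0.0001, 1.0 - (double)step / steps_total);
      ++step;
      int b = 1 + rng.below(window); // dynamic window
      for (int off = -b; off <= b; ++off) {
        if (off == 0) continue;
        int j = i + off;
        if (j < 0 || j >= corpus.size() || corpus[j] < 0) continue;
        int context = corpus[j];
        double* wv = &W[(size_t)center * d];
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int neg = 0; neg <= negative; ++neg) {
          int target;
          double label;
          if (neg == 0) { target = context; label = 1.0; }
          else {
            target = table[rng.below(TABLE)];
            if (target == context) continue;
            label = 0.0;
          }
          double* cv = &C[(size_t)target * d];
          double dot = 0.0;
          for (int k = 0; k < d; ++k) dot += wv[k] * cv[k];
          double sig = 1.0 / (1.0 + std::exp(-dot));
          double g = alpha * (label - sig);
          for (int k = 0; k < d; ++k) {
            grad[k] += g * cv[k];
            cv[k] += g * wv[k];
          }
        }
        for (int k = 0; k < d; ++k) wv[k] += grad[k];
      }
    }
  }
  NumericMatrix out(vocab_size, d);
  for (int v = 0; v < vocab_size; ++v) {
    for (int k = 0; k < d; ++k) out(v, k) = W[(size_t)v * d + k];
  }
  return out;
}
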