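#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Regression-forest "selection frequency" engine.
//
// Grows n_forests independent forests of n_trees CART regression trees on
// bootstrap samples of the rows, sampling mtry candidate features per node,
// and counts for every feature the number of trees in which it is chosen
// for at least one split. Features are binary haplotype codes (0/1), so the
// only split is x < 0.5 vs x >= 0.5; the best candidate by SSE reduction
// wins. Splits must leave at least min_leaf rows in each child.
//
// Uses R's RNG (unif_rand), so set.seed() in R makes runs reproducible.

namespace {

struct Node {
  int begin, end;  // range in idx
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export(name = ".forest_selection_frequency")]]
NumericVector forest_selection_frequency(const NumericMatrix& X,
                                         const NumericVector& y,
                                         int n_forests, int n_trees,
                                         int mtry, int min_leaf,
                                         bool root_only = false) {
  const int n = X.nrow(), p = X.ncol();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (n_forests < 1) stop("n_forests must be >= 1");
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, number of blocks]");
  if (min_leaf < 1) stop("min_leaf must be >= 1");

  std::vector<long> tree_count(p, 0);
  std::vector<int> idx(n), feat(p);
  std::vector<char> used(p);
  // column-major 0/1 genotype codes and phenotype, in flat arrays
  std::vector<signed char> xc((size_t)n * p);
  std::vector<double> yv(n);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      xc[(size_t)j * n + i] = X(i, j) >= 0.5 ? 1 : 0;
  for (int i = 0; i < n; ++i) yv[i] = y[i];

  for (int f = 0; f < n_forests; ++f) {
    for (int t = 0; t < n_trees; ++t) {
      // bootstrap sample of rows
      for (int i = 0; i < n; ++i) idx[i] = runif_int(n);
      std::fill(used.begin(), used.end(), 0);

      std::vector<Node> stack;
      stack.push_back({0, n});
      bool at_root = true;
      while (!stack.empty()) {
        Node node = stack.back();
        stack.pop_back();
        const int m = node.end - node.begin;
        if (m < 2 * min_leaf) { at_root = false; continue; }

        double sum = 0.0;
        for (int i = node.begin; i < node.end; ++i) sum += yv[idx[i]];

        // draw mtry distinct candidate features (partial Fisher-Yates)
        for (int j = 0; j < p; ++j) feat[j] = j;
        int best_f = -1;
        double best_gain = 0.0;
        for (int j = 0; j < mtry; ++j) {
          int k = j + runif_int(p - j);
          std::swap(feat[j], feat[k]);
          const int fcol = feat[j];
          const signed char* xcol = &xc[(size_t)fcol * n];
          double sum1 = 0.0;
          int n1 = 0;
          for (int i = node.begin; i < node.end; ++i) {
            const int r = idx[i];
            if (xcol[r]) { sum1 += yv[r]; ++n1; }
          }
          const int n0 = m - n1;
          if (n1 < min_leaf || n0 < min_leaf) continue;
          const double sum0 = sum - sum1;
          const double gain =
              sum0 * sum0 / n0 + sum1 * sum1 / n1 - sum * sum / m;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = fcol;
          }
        }
        if (best_f < 0) { at_root = false; continue; }
        if (!root_only || at_root) used[best_f] = 1;
        at_root = false;

        // partition rows: left = x == 0
        const signed char* xbest = &xc[(size_t)best_f * n];
        int mid = node.begin;
        for (int i = node.begin; i < node.end; ++i) {
          if (!xbest[idx[i]]) std::swap(idx[i], idx[mid++]);
        }
        stack.push_back({node.begin, mid});
        stack.push_back({mid, node.end});
      }

      for (int j = 0; j < p; ++j)
        if (used[j]) ++tree_count[j];
    }
  }

  NumericVector out(p);
  const double total = (double)n_forests * (double)n_trees;
  for (int j = 0; j < p; ++j) out[j] = tree_count[j] / total;
  return out;
}
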