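// Classification random forest (CART, Gini) with path-dependent TreeSHAP.
//
// Kept self-contained and deterministic: a splitmix64/xorshift PRNG seeded
// from R drives bootstrap and feature subsampling, so fits reproduce
// bit-identically for a fixed seed regardless of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// --- deterministic PRNG -----------------------------------------------------

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// --- tree structures --------------------------------------------------------

struct TreeNodes {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> cover;       // training samples (with multiplicity)
  std::vector<double> value;       // n_nodes * K class distribution
  int K;
  int max_depth_seen;
};

static void node_distribution(const std::vector<int>& idx,
                              const IntegerVector& y, int K,
                              std::vector<double>& out) {
  out.assign(K, 0.0);
  for (int i : idx) out[y[i]] += 1.0;
  double tot = static_cast<double>(idx.size());
  for (int k = 0; k < K; ++k) out[k] /= tot;
}

static double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (n * n);
}

static int grow_node(TreeNodes& T, const NumericMatrix& X,
                     const IntegerVector& y, std::vector<int>& idx,
                     int depth, int max_depth, int min_split, int min_leaf,
                     int mtry, Rng& rng) {
  const int K = T.K;
  const int node = static_cast<int>(T.feature.size());
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.cover.push_back(static_cast<double>(idx.size()));
  std::vector<double> dist;
  node_distribution(idx, y, K, dist);
  for (int k = 0; k < K; ++k) T.value.push_back(dist[k]);
  if (depth > T.max_depth_seen) T.max_depth_seen = depth;

  const int n = static_cast<int>(idx.size());
  bool pure = false;
  for (int k = 0; k < K; ++k) if (dist[k] >= 1.0 - 1e-12) pure = true;
  if (pure || n < min_split || (max_depth > 0 && depth >= max_depth)) {
    return node;
  }

  // candidate features: partial Fisher-Yates over column indices
  const int p = X.ncol();
  std::vector<int> cols(p);
  for (int j = 0; j < p; ++j) cols[j] = j;
  int ncand = std::min(mtry, p);
  for (int j = 0; j < ncand; ++j) {
    int r = j + rng.below(p - j);
    std::swap(cols[j], cols[r]);
  }

  std::vector<double> total_cnt(K, 0.0);
  for (int i : idx) total_cnt[y[i]] += 1.0;
  const double parent_gini = gini_from_counts(total_cnt, n);

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  std::vector<double> lcnt(K);
  for (int jj = 0; jj < ncand; ++jj) {
    const int f = cols[jj];
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::fill(lcnt.begin(), lcnt.end(), 0.0);
    for (int i = 0; i < n - 1; ++i) {
      lcnt[vals[i].second] += 1.0;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double gl = gini_from_counts(lcnt, nl);
      std::vector<double> rcnt(K);
      for (int k = 0; k < K; ++k) rcnt[k] = total_cnt[k] - lcnt[k];
      double gr = gini_from_counts(rcnt, nr);
      double gain = parent_gini - (nl * gl + nr * gr) / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  std::vector<int> lidx, ridx;
  for (int i : idx) {
    if (X(i, best_feat) <= best_thr) lidx.push_back(i);
    else ridx.push_back(i);
  }
  if (lidx.empty() || ridx.empty()) return node;
  T.feature[node] = best_feat;
  T.threshold[node] = best_thr;
  int lchild = grow_node(T, X, y, lidx, depth + 1, max_depth, min_split,
                         min_leaf, mtry, rng);
  T.left[node] = lchild;
  int rchild = grow_node(T, X, y, ridx, depth + 1, max_depth, min_split,
                         min_leaf, mtry, rng);
  T.right[node] = rchild;
  return node;
}

static List tree_to_list(const TreeNodes& T) {
  const int nn = static_cast<int>(T.feature.size());
  NumericMatrix val(nn, T.K);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < T.K; ++k) val(i, k) = T.value[i * T.K + k];
  return List::create(
    _["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
    _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
    _["left"] = IntegerVector(T.left.begin(), T.left.end()),
    _["right"] = IntegerVector(T.right.begin(), T.right.end()),
    _["cover"] = NumericVector(T.cover.begin(), T.cover.end()),
    _["value"] = val,
    _["max_depth"] = T.max_depth_seen);
}

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int n_classes,
                int n_trees, int mtry, int max_depth, int min_split,
                int min_leaf, double seed) {
  const int n = X.nrow();
  Rng rng(static_cast<uint64_t>(seed));
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);  // bootstrap
    std::sort(idx.begin(), idx.end());
    TreeNodes T;
    T.K = n_classes;
    T.max_depth_seen = 0;
    grow_node(T, X, y, idx, 0, max_depth, min_split, min_leaf, mtry, rng);
    trees[t] = tree_to_list(T);
  }
  return trees;
}

static int descend(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return node;
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_predict(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(feature, threshold, left, right, X, i);
      for (int k = 0; k < n_classes; ++k) out(i, k) += value(leaf, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_classes; ++k) out(i, k) /= T;
  return out;
}

// --- TreeSHAP (path-dependent) ----------------------------------------------

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement* path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1)
                           / static_cast<double>(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i)
                      / static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(PathElement* path, int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1)
                        / static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction
                         * (unique_depth - i)
                         / static_cast<double>(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1))
                        / (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement* path, int unique_depth,
                               int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1)
                         / static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction
                         * ((unique_depth - i)
                            / static_cast<double>(unique_depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction)
               / ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct TreeView {
  const int* feature;
  const double* threshold;
  const int* left;
  const int* right;
  const double* cover;
  const double* leaf_value;  // per-node scalar (one class' probability)
};

static void tree_shap_recursive(const TreeView& tree, const double* x,
                                double* phi, int node, int unique_depth,
                                PathElement* parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement* path = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth + 1, path);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tree.feature[node] < 0) {
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement& el = path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tree.leaf_value[node];
    }
    return;
  }

  const int f = tree.feature[node];
  const int hot = (x[f] <= tree.threshold[node]) ? tree.left[node]
                                                 : tree.right[node];
  const int cold = (hot == tree.left[node]) ? tree.right[node]
                                            : tree.left[node];
  const double hot_zero = tree.cover[hot] / tree.cover[node];
  const double cold_zero = tree.cover[cold] / tree.cover[node];
  double incoming_zero = 1.0, incoming_one = 1.0;
  int path_index = 0;
  while (path_index <= unique_depth &&
         path[path_index].feature_index != f) {
    ++path_index;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  tree_shap_recursive(tree, x, phi, hot, unique_depth + 1, path,
                      hot_zero * incoming_zero, incoming_one, f);
  tree_shap_recursive(tree, x, phi, cold, unique_depth + 1, path,
                      cold_zero * incoming_zero, 0.0, f);
}

// Per-class SHAP values for every row of X.
// Returns a list of n_classes matrices (n x p) plus per-class base values.
// [[Rcpp::export]]
List cpp_rf_shap(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  List phis(n_classes);
  NumericVector base(n_classes);
  std::vector<NumericMatrix> phi_mats;
  for (int k = 0; k < n_classes; ++k) phi_mats.push_back(NumericMatrix(n, p));

  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector cover = tr["cover"];
    NumericMatrix value = tr["value"];
    int maxd = as<int>(tr["max_depth"]);
    const int bufn = (maxd + 2) * (maxd + 3) / 2 + maxd + 2;
    std::vector<PathElement> buf(bufn);
    const int nn = feature.size();
    std::vector<double> leaf_val(nn);
    for (int k = 0; k < n_classes; ++k) {
      for (int j = 0; j < nn; ++j) leaf_val[j] = value(j, k);
      base[k] += value(0, k);
      TreeView tv{feature.begin(), threshold.begin(), left.begin(),
                  right.begin(), cover.begin(), leaf_val.data()};
      std::vector<double> xrow(p), phirow(p);
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
        std::fill(phirow.begin(), phirow.end(), 0.0);
        tree_shap_recursive(tv, xrow.data(), phirow.data(), 0, 0,
                            buf.data(), 1.0, 1.0, -1);
        for (int j = 0; j < p; ++j) phi_mats[k](i, j) += phirow[j];
      }
    }
  }
  for (int k = 0; k < n_classes; ++k) {
    NumericMatrix& m = phi_mats[k];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < p; ++j) m(i, j) /= T;
    base[k] /= T;
    phis[k] = m;
  }
  return List::create(_["phi"] = phis, _["base"] = base);
}
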