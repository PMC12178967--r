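// Exact TreeSHAP (interventional-path algorithm of Lundberg et al.) for
// additive regression-tree ensembles, in double precision throughout so
// that per-row additivity (bias + sum of attributions = prediction) holds
// to machine precision. Split comparisons replicate the float32 semantics
// of the training library: both the feature value and the threshold are
// cast to float before comparing, otherwise rows whose value equals a
// stored threshold can be routed differently than at prediction time.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> left, right, split_index;
  std::vector<int> default_left;
  std::vector<double> thresh, value, cover;
};

struct PathElem {
  int d;       // feature index (-1 for the root placeholder)
  double z;    // fraction of zero (cold) paths flowing through
  double o;    // fraction of one (hot) paths flowing through
  double w;    // permutation weight
};

static void extend_path(std::vector<PathElem> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].d = feature_index;
  path[unique_depth].z = zero_fraction;
  path[unique_depth].o = one_fraction;
  path[unique_depth].w = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].w += one_fraction * path[i].w * (i + 1.0) /
                     (unique_depth + 1.0);
    path[i].w = zero_fraction * path[i].w * (unique_depth - i) /
                (unique_depth + 1.0);
  }
}

static void unwind_path(std::vector<PathElem> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].o;
  const double zero_fraction = path[path_index].z;
  double next_one_portion = path[unique_depth].w;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].w;
      path[i].w = next_one_portion * (unique_depth + 1.0) /
                  ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].w * zero_fraction *
                               (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].w = (path[i].w * (unique_depth + 1.0)) /
                  (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].d = path[i + 1].d;
    path[i].z = path[i + 1].z;
    path[i].o = path[i + 1].o;
  }
}

static double unwound_path_sum(const std::vector<PathElem> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].o;
  const double zero_fraction = path[path_index].z;
  double next_one_portion = path[unique_depth].w;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) /
                         ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].w - tmp * zero_fraction *
                         ((unique_depth - i) / (unique_depth + 1.0));
    } else {
      total += (path[i].w / zero_fraction) /
               ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

static void tree_shap_recurse(const Tree &t, const double *x, double *phi,
                              int node, int unique_depth,
                              std::vector<PathElem> path,  // by value: copy
                              double parent_zero_fraction,
                              double parent_one_fraction,
                              int parent_feature_index) {
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);
  if (t.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * t.value[node];
    }
    return;
  }
  const int split = t.split_index[node];
  const double v = x[split];
  int hot;
  if (ISNAN(v)) {
    hot = t.default_left[node] ? t.left[node] : t.right[node];
  } else {
    hot = (static_cast<float>(v) < static_cast<float>(t.thresh[node]))
              ? t.left[node]
              : t.right[node];
  }
  const int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  const double hot_zero_fraction = t.cover[hot] / t.cover[node];
  const double cold_zero_fraction = t.cover[cold] / t.cover[node];
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (path[path_index].d == split) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].z;
    incoming_one_fraction = path[path_index].o;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  tree_shap_recurse(t, x, phi, hot, unique_depth + 1, path,
                    hot_zero_fraction * incoming_zero_fraction,
                    incoming_one_fraction, split);
  tree_shap_recurse(t, x, phi, cold, unique_depth + 1, path,
                    cold_zero_fraction * incoming_zero_fraction, 0.0, split);
}

static std::vector<Tree> parse_forest(List trees) {
  std::vector<Tree> forest(trees.size());
  for (int m = 0; m < trees.size(); ++m) {
    List tr = trees[m];
    Tree &t = forest[m];
    t.left = as<std::vector<int> >(tr["left"]);
    t.right = as<std::vector<int> >(tr["right"]);
    t.split_index = as<std::vector<int> >(tr["split_index"]);
    t.default_left = as<std::vector<int> >(tr["default_left"]);
    t.thresh = as<std::vector<double> >(tr["threshold"]);
    t.value = as<std::vector<double> >(tr["value"]);
    t.cover = as<std::vector<double> >(tr["cover"]);
  }
  return forest;
}

static int forest_max_depth(const Tree &t, int node, int depth) {
  if (t.left[node] < 0) return depth;
  int dl = forest_max_depth(t, t.left[node], depth + 1);
  int dr = forest_max_depth(t, t.right[node], depth + 1);
  return dl > dr ? dl : dr;
}

static double leaf_for_row(const Tree &t, const double *x) {
  int node = 0;
  while (t.left[node] >= 0) {
    const double v = x[t.split_index[node]];
    if (ISNAN(v)) {
      node = t.default_left[node] ? t.left[node] : t.right[node];
    } else {
      node = (static_cast<float>(v) < static_cast<float>(t.thresh[node]))
                 ? t.left[node]
                 : t.right[node];
    }
  }
  return t.value[node];
}

// [[Rcpp::export]]
NumericMatrix treeshap_cpp(List trees, NumericMatrix x, double base_score) {
  const std::vector<Tree> forest = parse_forest(trees);
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p + 1);

  // expected value (cover-weighted leaf mean) per tree -> bias column
  double expected = base_score;
  for (size_t m = 0; m < forest.size(); ++m) {
    const Tree &t = forest[m];
    double e = 0.0;
    for (size_t j = 0; j < t.left.size(); ++j) {
      if (t.left[j] < 0) e += t.cover[j] / t.cover[0] * t.value[j];
    }
    expected += e;
  }

  int max_depth = 0;
  for (size_t m = 0; m < forest.size(); ++m) {
    const int d = forest_max_depth(forest[m], 0, 0);
    if (d > max_depth) max_depth = d;
  }

  std::vector<double> row(p), phi(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = x(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (size_t m = 0; m < forest.size(); ++m) {
      std::vector<PathElem> path(max_depth + 2);
      tree_shap_recurse(forest[m], row.data(), phi.data(), 0, 0, path, 1.0,
                        1.0, -1);
    }
    for (int j = 0; j < p; ++j) out(i, j) = phi[j];
    out(i, p) = expected;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix x,
                                 double base_score) {
  const std::vector<Tree> forest = parse_forest(trees);
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = x(i, j);
    double s = base_score;
    for (size_t m = 0; m < forest.size(); ++m) {
      s += leaf_for_row(forest[m], row.data());
    }
    out[i] = s;
  }
  return out;
}
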