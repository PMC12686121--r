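#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Path-dependent tree Shapley attribution for binary decision trees.
//
// A forest is a list of trees; each tree is a list of aligned vectors
// describing nodes 0..m-1:
//   left, right : integer child ids (-1 at leaves)
//   feature     : 0-based split feature (-1 at leaves)
//   threshold   : split value (x goes left when x <= threshold, or x <
//                 threshold when le_split = FALSE, matching xgboost)
//   value       : leaf output (ignored at internal nodes)
//   cover       : node weight (training samples routed through the node)
//
// The recursion keeps, for every feature on the current root-to-node path,
// the fraction of coalition-weighted paths that flow through when the
// feature is known ("one fraction") versus marginalised by cover
// ("zero fraction"), extending/unwinding a shared permutation-weight path.
// Conditioning (condition = +1 / -1) fixes a feature as always-known /
// always-unknown, which yields pairwise interaction values by differencing.

struct PathElem {
  int fi;
  double pz;
  double po;
  double pw;
};

struct Tree {
  std::vector<int> left, right, feature;
  std::vector<double> thr, value, cover;
};

static void extend_path(std::vector<PathElem> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].fi = feature_index;
  path[unique_depth].pz = zero_fraction;
  path[unique_depth].po = one_fraction;
  path[unique_depth].pw = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pw += one_fraction * path[i].pw * (i + 1.0) / (unique_depth + 1.0);
    path[i].pw = zero_fraction * path[i].pw * (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(std::vector<PathElem> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].po;
  const double zero_fraction = path[path_index].pz;
  double next_one_portion = path[unique_depth].pw;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = path[i].pw;
      path[i].pw = next_one_portion * (unique_depth + 1.0) / ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pw * zero_fraction * (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].pw = (path[i].pw * (unique_depth + 1.0)) / (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].fi = path[i + 1].fi;
    path[i].pz = path[i + 1].pz;
    path[i].po = path[i + 1].po;
  }
}

static double unwound_path_sum(const std::vector<PathElem> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].po;
  const double zero_fraction = path[path_index].pz;
  double next_one_portion = path[unique_depth].pw;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pw - tmp * zero_fraction * (unique_depth - i) / (unique_depth + 1.0);
    } else if (zero_fraction != 0.0) {
      total += (path[i].pw / zero_fraction) / ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

static void shap_recurse(const Tree &t, int node, std::vector<PathElem> path,
                         int unique_depth, double parent_zero_fraction,
                         double parent_one_fraction, int parent_feature_index,
                         const double *x, double *phi, int condition,
                         int condition_feature, double condition_fraction,
                         bool le_split) {
  if (condition_fraction == 0.0) return;
  if (condition == 0 || condition_feature != parent_feature_index) {
    extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
                parent_feature_index);
  }
  const int f = t.feature[node];
  if (f < 0) {
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[path[i].fi] +=
          w * (path[i].po - path[i].pz) * t.value[node] * condition_fraction;
    }
    return;
  }
  const double xv = x[f];
  const bool go_left = le_split ? (xv <= t.thr[node]) : (xv < t.thr[node]);
  const int hot = go_left ? t.left[node] : t.right[node];
  const int cold = go_left ? t.right[node] : t.left[node];
  const double w = t.cover[node];
  const double hot_zero_fraction = t.cover[hot] / w;
  const double cold_zero_fraction = t.cover[cold] / w;
  double incoming_zero_fraction = 1.0, incoming_one_fraction = 1.0;

  int path_index = 0;
  while (path_index <= unique_depth) {
    if (path[path_index].fi == f) break;
    ++path_index;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].pz;
    incoming_one_fraction = path[path_index].po;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  double hot_condition_fraction = condition_fraction;
  double cold_condition_fraction = condition_fraction;
  if (condition > 0 && f == condition_feature) {
    cold_condition_fraction = 0.0;
    unique_depth -= 1;
  } else if (condition < 0 && f == condition_feature) {
    hot_condition_fraction *= hot_zero_fraction;
    cold_condition_fraction *= cold_zero_fraction;
    unique_depth -= 1;
  }

  shap_recurse(t, hot, path, unique_depth + 1,
               hot_zero_fraction * incoming_zero_fraction, incoming_one_fraction,
               f, x, phi, condition, condition_feature, hot_condition_fraction,
               le_split);
  shap_recurse(t, cold, path, unique_depth + 1,
               cold_zero_fraction * incoming_zero_fraction, 0.0, f, x, phi,
               condition, condition_feature, cold_condition_fraction, le_split);
}

static Tree parse_tree(List tl) {
  Tree t;
  IntegerVector left = tl["left"], right = tl["right"], feature = tl["feature"];
  NumericVector thr = tl["threshold"], value = tl["value"], cover = tl["cover"];
  t.left = as<std::vector<int> >(left);
  t.right = as<std::vector<int> >(right);
  t.feature = as<std::vector<int> >(feature);
  t.thr = as<std::vector<double> >(thr);
  t.value = as<std::vector<double> >(value);
  t.cover = as<std::vector<double> >(cover);
  return t;
}

static int tree_depth(const Tree &t, int node) {
  if (t.feature[node] < 0) return 1;
  const int dl = tree_depth(t, t.left[node]);
  const int dr = tree_depth(t, t.right[node]);
  return 1 + (dl > dr ? dl : dr);
}

static double tree_expected_value(const Tree &t) {
  // cover-weighted mean of leaf values
  double total = 0.0;
  for (size_t j = 0; j < t.feature.size(); ++j) {
    if (t.feature[j] < 0) total += t.value[j] * t.cover[j];
  }
  return total / t.cover[0];
}

static void tree_phi(const Tree &t, int maxd, const double *x, double *phi,
                     int condition, int condition_feature, bool le_split) {
  std::vector<PathElem> path(maxd + 2);
  shap_recurse(t, 0, path, 0, 1.0, 1.0, -1, x, phi, condition,
               condition_feature, 1.0, le_split);
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
NumericMatrix treeshap_cpp(List forest, NumericMatrix X, bool le_split = true) {
  const int n = X.nrow(), p = X.ncol(), ntree = forest.size();
  std::vector<Tree> trees(ntree);
  std::vector<int> depths(ntree);
  double base = 0.0;
  for (int k = 0; k < ntree; ++k) {
    trees[k] = parse_tree(forest[k]);
    depths[k] = tree_depth(trees[k], 0);
    base += tree_expected_value(trees[k]);
  }
  base /= ntree;

  NumericMatrix out(n, p + 1);
  std::vector<double> x(p), phi(p);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) x[j] = X(r, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int k = 0; k < ntree; ++k)
      tree_phi(trees[k], depths[k], x.data(), phi.data(), 0, -1, le_split);
    for (int j = 0; j < p; ++j) out(r, j) = phi[j] / ntree;
    out(r, p) = base;
  }
  return out;
}

// [[Rcpp::export(name = ".treeshap_interactions_cpp")]]
NumericVector treeshap_interactions_cpp(List forest, NumericMatrix X,
                                        bool le_split = true) {
  const int n = X.nrow(), p = X.ncol(), ntree = forest.size();
  std::vector<Tree> trees(ntree);
  std::vector<int> depths(ntree);
  for (int k = 0; k < ntree; ++k) {
    trees[k] = parse_tree(forest[k]);
    depths[k] = tree_depth(trees[k], 0);
  }

  NumericVector out(n * p * p);
  out.attr("dim") = IntegerVector::create(n, p, p);
  std::vector<double> x(p), phi(p), on(p), off(p);

  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) x[j] = X(r, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int k = 0; k < ntree; ++k)
      tree_phi(trees[k], depths[k], x.data(), phi.data(), 0, -1, le_split);

    std::vector<double> inter(p * p, 0.0);
    for (int i = 0; i < p; ++i) {
      std::fill(on.begin(), on.end(), 0.0);
      std::fill(off.begin(), off.end(), 0.0);
      for (int k = 0; k < ntree; ++k) {
        tree_phi(trees[k], depths[k], x.data(), on.data(), 1, i, le_split);
        tree_phi(trees[k], depths[k], x.data(), off.data(), -1, i, le_split);
      }
      double row_sum = 0.0;
      for (int j = 0; j < p; ++j) {
        if (j == i) continue;
        const double v = (on[j] - off[j]) / 2.0;
        inter[i * p + j] = v;
        row_sum += v;
      }
      inter[i * p + i] = phi[i] / ntree - row_sum / ntree;
      for (int j = 0; j < p; ++j)
        if (j != i) inter[i * p + j] /= ntree;
    }
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) out[r + n * (i + p * j)] = inter[i * p + j];
  }
  return out;
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List forest, NumericMatrix X,
                               bool le_split = true) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int k = 0; k < ntree; ++k) {
    Tree t = parse_tree(forest[k]);
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while (t.feature[node] >= 0) {
        const double xv = X(r, t.feature[node]);
        const bool go_left = le_split ? (xv <= t.thr[node]) : (xv < t.thr[node]);
        node = go_left ? t.left[node] : t.right[node];
      }
      out[r] += t.value[node];
    }
  }
  return out / ntree;
}
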