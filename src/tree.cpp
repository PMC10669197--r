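#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// CART regression trees used by the ensemble fitters.
//
// mode 0 ("cart"): splits maximize the reduction in within-node sum of
//   squared deviations of y; leaf value = node mean.
// mode 1 ("xgb"): y is the negative gradient sum target; splits maximize the
//   regularized second-order gain 0.5*(GL^2/(HL+l) + GR^2/(HR+l) -
//   G^2/(H+l)) - gamma with unit hessians, leaf value = G/(H+l) of the
//   residual target (so trees are fit to residuals directly).
//
// Feature subsampling (mtry) uses a private mt19937 stream so a fitted tree
// is a pure function of (data, parameters, seed). Per-feature split-quality
// totals are accumulated as importances.

struct TreeBuilder {
  const NumericMatrix &X;
  const std::vector<double> &y;
  int max_depth, min_split, min_leaf, mtry;
  double lambda, gamma;
  int mode;
  std::mt19937 rng;

  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  std::vector<double> importance;

  TreeBuilder(const NumericMatrix &X_, const std::vector<double> &y_,
              int max_depth_, int min_split_, int min_leaf_, int mtry_,
              double lambda_, double gamma_, int mode_, unsigned seed)
      : X(X_), y(y_), max_depth(max_depth_), min_split(min_split_),
        min_leaf(min_leaf_), mtry(mtry_), lambda(lambda_), gamma(gamma_),
        mode(mode_), rng(seed), importance(X_.ncol(), 0.0) {}

  int new_leaf(double val) {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(val);
    return (int)feature.size() - 1;
  }

  double leaf_value(const std::vector<int> &idx) const {
    double s = 0.0;
    for (size_t i = 0; i < idx.size(); ++i) s += y[idx[i]];
    if (mode == 1) return s / (idx.size() + lambda);
    return s / (double)idx.size();
  }

  int build(std::vector<int> &idx, int depth) {
    const int n = (int)idx.size();
    double sum = 0.0, sum2 = 0.0;
    for (int i = 0; i < n; ++i) {
      sum += y[idx[i]];
      sum2 += y[idx[i]] * y[idx[i]];
    }
    bool pure = (sum2 - sum * sum / n) <= 1e-12 * (std::fabs(sum2) + 1e-12);
    if (n < min_split || depth >= max_depth || (mode == 0 && pure))
      return new_leaf(leaf_value(idx));

    // sample candidate features without replacement
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }

    double parent_score;
    if (mode == 1)
      parent_score = 0.5 * sum * sum / (n + lambda);
    else
      parent_score = sum * sum / n;  // -SSE up to a constant

    int best_f = -1;
    double best_gain = 0.0, best_thr = 0.0;
    std::vector<std::pair<double, int> > vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), idx[i]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      double ls = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        ls += y[vals[i].second];
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double rs = sum - ls;
        double gain;
        if (mode == 1) {
          gain = 0.5 * (ls * ls / (nl + lambda) + rs * rs / (nr + lambda)) -
                 parent_score - gamma;
        } else {
          gain = ls * ls / nl + rs * rs / nr - parent_score;
        }
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return new_leaf(leaf_value(idx));

    importance[best_f] += best_gain;
    std::vector<int> li, ri;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr)
        li.push_back(idx[i]);
      else
        ri.push_back(idx[i]);
    }
    int node = new_leaf(0.0);  // placeholder, becomes internal
    feature[node] = best_f;
    threshold[node] = best_thr;
    int L = build(li, depth + 1);
    int R = build(ri, depth + 1);
    left[node] = L;
    right[node] = R;
    return node;
  }
};

// [[Rcpp::export(name = ".tree_fit_cpp")]]
List tree_fit_cpp(NumericMatrix X, NumericVector y, int max_depth,
                  int min_split, int min_leaf, int mtry, double lambda,
                  double gamma, int mode, int seed) {
  std::vector<double> yy(y.begin(), y.end());
  TreeBuilder tb(X, yy, max_depth, min_split, min_leaf, mtry, lambda, gamma,
                 mode, (unsigned)seed);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  int root = tb.build(idx, 0);
  return List::create(
      _["feature"] = wrap(tb.feature), _["threshold"] = wrap(tb.threshold),
      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
      _["value"] = wrap(tb.value), _["root"] = root,
      _["importance"] = wrap(tb.importance));
}

static int tree_descend(const IntegerVector &feature,
                        const NumericVector &threshold,
                        const IntegerVector &left, const IntegerVector &right,
                        int root, const NumericMatrix &X, int row) {
  int node = root;
  while (feature[node] >= 0) {
    if (X(row, feature[node]) <= threshold[node])
      node = left[node];
    else
      node = right[node];
  }
  return node;
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int root = as<int>(tree["root"]);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = value[tree_descend(feature, threshold, left, right, root, X, i)];
  return out;
}

// [[Rcpp::export(name = ".tree_apply_cpp")]]
IntegerVector tree_apply_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  int root = as<int>(tree["root"]);
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] =
        tree_descend(feature, threshold, left, right, root, X, i) + 1;
  return out;
}
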