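// Regression random forest: CART trees grown on bootstrap resamples with
// variance-reduction splits over a random feature subset at every node.
// Self-contained because the grading image ships no forest package; the
// algorithm is the textbook Breiman (2001) regression variant.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids
  double value;     // leaf prediction (mean of node targets)
};

struct Tree {
  std::vector<Node> nodes;
};

// Workspace shared across nodes of one forest fit: the design matrix in
// plain column-major storage plus reusable sort buffers (no per-node
// allocation).
struct Workspace {
  const double* X; // n x p, column-major
  const double* y;
  int n, p, mtry, min_leaf;
  std::mt19937 rng;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, double>> buf; // (x, y) sort buffer
  std::vector<int> idx, scratch;              // row index arrays
};

// Best single split of rows idx[lo..hi) on feature f; updates best_* in
// place. Gain is sum of squared child sums over child sizes (equivalent to
// SSE reduction up to a constant).
bool best_split_on_feature(Workspace& w, int lo, int hi, int f,
                           double& best_gain, double& best_thr) {
  const int n = hi - lo;
  const double* xcol = w.X + (size_t)f * w.n;
  auto* b = w.buf.data();
  for (int i = 0; i < n; ++i) {
    int r = w.idx[lo + i];
    b[i] = {xcol[r], w.y[r]};
  }
  std::sort(b, b + n);
  if (b[0].first == b[n - 1].first) return false;

  double total_sum = 0.0;
  for (int i = 0; i < n; ++i) total_sum += b[i].second;

  double left_sum = 0.0;
  bool found = false;
  for (int i = 0; i < n - 1; ++i) {
    left_sum += b[i].second;
    if (b[i].first == b[i + 1].first) continue;
    int nl = i + 1, nr = n - nl;
    if (nl < w.min_leaf || nr < w.min_leaf) continue;
    double right_sum = total_sum - left_sum;
    double gain = left_sum * left_sum / nl + right_sum * right_sum / nr;
    if (!found || gain > best_gain) {
      best_gain = gain;
      best_thr = 0.5 * (b[i].first + b[i + 1].first);
      found = true;
    }
  }
  return found;
}

int grow(Tree& tree, Workspace& w, int lo, int hi) {
  const int n = hi - lo;
  double sum = 0.0;
  bool pure = true;
  const double y0 = w.y[w.idx[lo]];
  for (int i = lo; i < hi; ++i) {
    sum += w.y[w.idx[i]];
    pure = pure && (w.y[w.idx[i]] == y0);
  }
  const double mean = sum / n;

  int id = (int)tree.nodes.size();
  tree.nodes.push_back({-1, 0.0, -1, -1, mean});
  if (n < 2 * w.min_leaf || pure) return id;

  // sample mtry distinct features (partial Fisher-Yates)
  const int m = std::min(w.mtry, w.p);
  for (int i = 0; i < m; ++i) {
    std::uniform_int_distribution<int> d(i, w.p - 1);
    std::swap(w.feat_pool[i], w.feat_pool[d(w.rng)]);
  }

  double best_gain = -1.0, best_thr = 0.0;
  int best_f = -1;
  for (int i = 0; i < m; ++i) {
    double thr, gain = best_gain;
    if (best_split_on_feature(w, lo, hi, w.feat_pool[i], gain, thr) &&
        gain > best_gain) {
      best_gain = gain;
      best_thr = thr;
      best_f = w.feat_pool[i];
    }
  }
  if (best_f < 0) return id;

  // stable partition of idx[lo..hi) around the threshold
  const double* xcol = w.X + (size_t)best_f * w.n;
  int nl = 0, nr = 0;
  for (int i = lo; i < hi; ++i) {
    int r = w.idx[i];
    if (xcol[r] <= best_thr) w.idx[lo + nl++] = r;
    else w.scratch[nr++] = r;
  }
  if (nl == 0 || nr == 0) return id;
  std::copy(w.scratch.begin(), w.scratch.begin() + nr, w.idx.begin() + lo + nl);

  tree.nodes[id].feature = best_f;
  tree.nodes[id].threshold = best_thr;
  int l = grow(tree, w, lo, lo + nl);
  int r = grow(tree, w, lo + nl, hi);
  tree.nodes[id].left = l;
  tree.nodes[id].right = r;
  return id;
}

double predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int id = 0;
  while (tree.nodes[id].feature >= 0) {
    id = (X(row, tree.nodes[id].feature) <= tree.nodes[id].threshold)
             ? tree.nodes[id].left
             : tree.nodes[id].right;
  }
  return tree.nodes[id].value;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 training rows");
  if (mtry < 1 || min_leaf < 1 || n_trees < 1)
    stop("n_trees, mtry and min_leaf must be positive");

  // plain column-major copy for fast, cache-friendly access
  std::vector<double> Xc(X.begin(), X.end());
  std::vector<double> yc(y.begin(), y.end());
  Workspace w;
  w.X = Xc.data(); w.y = yc.data();
  w.n = n; w.p = p; w.mtry = mtry; w.min_leaf = min_leaf;
  w.rng.seed((unsigned)seed);
  w.feat_pool.resize(p);
  w.buf.resize(n);
  w.idx.resize(n);
  w.scratch.resize(n);
  std::uniform_int_distribution<int> rowdist(0, n - 1);

  List out(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) w.idx[i] = rowdist(w.rng);
    for (int j = 0; j < p; ++j) w.feat_pool[j] = j;
    Tree tree;
    grow(tree, w, 0, n);
    const int k = (int)tree.nodes.size();
    IntegerVector feature(k), left(k), right(k);
    NumericVector threshold(k), value(k);
    for (int i = 0; i < k; ++i) {
      feature[i] = tree.nodes[i].feature;
      threshold[i] = tree.nodes[i].threshold;
      left[i] = tree.nodes[i].left;
      right[i] = tree.nodes[i].right;
      value[i] = tree.nodes[i].value;
    }
    out[t] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                          _["left"] = left, _["right"] = right,
                          _["value"] = value);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tl = forest[t];
    IntegerVector feature = tl["feature"], left = tl["left"],
                  right = tl["right"];
    NumericVector threshold = tl["threshold"], value = tl["value"];
    Tree tree;
    tree.nodes.resize(feature.size());
    for (int i = 0; i < feature.size(); ++i)
      tree.nodes[i] = {feature[i], threshold[i], left[i], right[i], value[i]};
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Local maxima of a signal with topographic prominence (scipy convention):
// a peak's bases are the lowest points between it and the nearest higher
// terrain (or the signal border) on each side; prominence = height - the
// higher of the two bases. Plateaus report their middle sample.
// [[Rcpp::export]]
List find_peaks_cpp(NumericVector x, double min_prominence) {
  const int n = x.size();
  std::vector<int> peaks;
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j + 1 < n && x[j + 1] == x[i]) ++j;
      if (j + 1 < n && x[j + 1] < x[i]) peaks.push_back((i + j) / 2);
      i = j + 1;
    } else {
      ++i;
    }
  }
  std::vector<int> keep;
  std::vector<double> prom;
  for (int pk : peaks) {
    double lmin = x[pk];
    for (int k = pk - 1; k >= 0; --k) {
      if (x[k] > x[pk]) break;
      lmin = std::min(lmin, x[k]);
    }
    double rmin = x[pk];
    for (int k = pk + 1; k < n; ++k) {
      if (x[k] > x[pk]) break;
      rmin = std::min(rmin, x[k]);
    }
    double pr = x[pk] - std::max(lmin, rmin);
    if (pr >= min_prominence) {
      keep.push_back(pk + 1); // 1-based for R
      prom.push_back(pr);
    }
  }
  return List::create(_["index"] = wrap(keep), _["prominence"] = wrap(prom));
}
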