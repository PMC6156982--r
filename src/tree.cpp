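#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Variance-reduction CART for regression.
//
// A node's impurity is its sum of squared deviations (SS); a split's gain is
// SS(parent) - SS(left) - SS(right), evaluated from prefix sums over the
// node's rows sorted by the candidate feature. Both children must keep at
// least min_leaf rows. Ties are broken deterministically: the lowest feature
// index wins (candidate features are scanned in ascending order) and, within
// a feature, the lowest threshold (strict improvement required in the scan).
// Feature subsampling draws from R's RNG so forests are reproducible under
// set.seed().

struct Node {
  int var;          // split feature (0-based), -1 for leaf
  double threshold; // goes left if x <= threshold
  double pred;      // node mean (training rows)
  double gain;      // training impurity reduction of this split
  int n;            // training rows in node
  int left, right;  // child node ids, -1 for leaf
};

static void best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& rows,
                       const std::vector<int>& feats, int min_leaf,
                       int& best_var, double& best_thr, double& best_gain) {
  const int m = rows.size();
  best_var = -1; best_thr = 0.0; best_gain = 1e-12;
  double sum = 0.0, sum2 = 0.0;
  for (int r : rows) { sum += y[r]; sum2 += y[r] * y[r]; }
  double ss_parent = sum2 - sum * sum / m;
  if (ss_parent <= 1e-12) return;

  std::vector<std::pair<double, double> > xy(m);
  for (int j : feats) {
    for (int i = 0; i < m; ++i) {
      xy[i].first = X(rows[i], j);
      xy[i].second = y[rows[i]];
    }
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double cum = 0.0, cum2 = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      cum += xy[i].second;
      cum2 += xy[i].second * xy[i].second;
      int nl = i + 1, nr = m - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      if (xy[i].first == xy[i + 1].first) continue;
      double ss_l = cum2 - cum * cum / nl;
      double sr = sum - cum, sr2 = sum2 - cum2;
      double ss_r = sr2 - sr * sr / nr;
      double gain = ss_parent - ss_l - ss_r;
      if (gain > best_gain) {
        best_gain = gain;
        best_var = j;
        best_thr = (xy[i].first + xy[i + 1].first) / 2.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows0,
                   int min_leaf, int mtry) {
  const int p = X.ncol();
  std::vector<Node> nodes;
  std::vector<std::vector<int> > node_rows;
  {
    std::vector<int> all(rows0.size());
    for (int i = 0; i < rows0.size(); ++i) all[i] = rows0[i] - 1;
    node_rows.push_back(all);
    Node root; root.var = -1; root.threshold = 0; root.gain = 0;
    root.n = all.size(); root.left = root.right = -1;
    double s = 0; for (int r : all) s += y[r];
    root.pred = s / all.size();
    nodes.push_back(root);
  }
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;

  for (size_t k = 0; k < nodes.size(); ++k) {
    std::vector<int>& rows = node_rows[k];
    if ((int)rows.size() < 2 * min_leaf) { node_rows[k].shrink_to_fit(); continue; }
    std::vector<int> cand;
    if (mtry >= p) {
      cand = feats;
    } else {
      // partial Fisher-Yates from R's RNG, then sorted for deterministic
      // tie-breaking by column index
      std::vector<int> pool(feats);
      cand.reserve(mtry);
      int npool = p;
      for (int t = 0; t < mtry; ++t) {
        int idx = (int)(unif_rand() * npool);
        if (idx >= npool) idx = npool - 1;
        cand.push_back(pool[idx]);
        pool[idx] = pool[--npool];
      }
      std::sort(cand.begin(), cand.end());
    }
    int bv; double bt, bg;
    best_split(X, y, rows, cand, min_leaf, bv, bt, bg);
    if (bv < 0) { continue; }
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, bv) <= bt) lrows.push_back(r); else rrows.push_back(r);
    }
    Node l, r;
    l.var = r.var = -1; l.threshold = r.threshold = 0;
    l.gain = r.gain = 0; l.left = l.right = r.left = r.right = -1;
    l.n = lrows.size(); r.n = rrows.size();
    double sl = 0; for (int q : lrows) sl += y[q];
    double sr = 0; for (int q : rrows) sr += y[q];
    l.pred = sl / l.n; r.pred = sr / r.n;
    nodes[k].var = bv; nodes[k].threshold = bt; nodes[k].gain = bg;
    nodes[k].left = nodes.size(); nodes.push_back(l); node_rows.push_back(lrows);
    nodes[k].right = nodes.size(); nodes.push_back(r); node_rows.push_back(rrows);
    std::vector<int>().swap(node_rows[k]);
  }

  const int nn = nodes.size();
  IntegerVector var(nn), nv(nn), left(nn), right(nn);
  NumericVector thr(nn), pred(nn), gain(nn);
  NumericVector importance(p);
  for (int i = 0; i < nn; ++i) {
    var[i] = nodes[i].var; thr[i] = nodes[i].threshold;
    pred[i] = nodes[i].pred; gain[i] = nodes[i].gain;
    nv[i] = nodes[i].n; left[i] = nodes[i].left; right[i] = nodes[i].right;
    if (nodes[i].var >= 0) importance[nodes[i].var] += nodes[i].gain;
  }
  return List::create(_["var"] = var, _["threshold"] = thr,
                      _["pred"] = pred, _["gain"] = gain, _["n"] = nv,
                      _["left"] = left, _["right"] = right,
                      _["importance"] = importance);
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"], pred = tree["pred"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (var[k] >= 0) {
      k = (X(i, var[k]) <= thr[k]) ? left[k] : right[k];
    }
    out[i] = pred[k];
  }
  return out;
}

// Impurity reduction of each stored split, re-evaluated on an arbitrary set
// of rows (e.g. a validation partition); summed per feature.
// [[Rcpp::export(name = ".tree_importance_cpp")]]
NumericVector tree_importance_cpp(List tree, NumericMatrix X,
                                  NumericVector y, IntegerVector rows0,
                                  int p) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"];
  const int nn = var.size();
  std::vector<std::vector<int> > node_rows(nn);
  for (int i = 0; i < rows0.size(); ++i) node_rows[0].push_back(rows0[i] - 1);
  NumericVector importance(p);
  for (int k = 0; k < nn; ++k) {
    if (var[k] < 0) continue;
    const std::vector<int>& rows = node_rows[k];
    if (rows.empty()) continue;
    double sum = 0, sum2 = 0, sl = 0, sl2 = 0;
    int nl = 0;
    for (int r : rows) {
      double yy = y[r];
      sum += yy; sum2 += yy * yy;
      if (X(r, var[k]) <= thr[k]) {
        node_rows[left[k]].push_back(r);
        sl += yy; sl2 += yy * yy; ++nl;
      } else {
        node_rows[right[k]].push_back(r);
      }
    }
    int m = rows.size(), nr = m - nl;
    double ss_p = sum2 - sum * sum / m;
    double ss_l = (nl > 0) ? sl2 - sl * sl / nl : 0.0;
    double sr = sum - sl, sr2 = sum2 - sl2;
    double ss_r = (nr > 0) ? sr2 - sr * sr / nr : 0.0;
    importance[var[k]] += ss_p - ss_l - ss_r;
  }
  return importance;
}
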