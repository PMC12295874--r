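#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Greedy binary tree induction used by the Monte Carlo feature-selection
// driver. Classification splits maximise Shannon information gain in bits;
// regression splits maximise population-variance reduction. Thresholds are
// midpoints of consecutive distinct sorted values; ties between candidate
// splits are broken towards the lower column index (the R driver passes
// projection columns in lexicographic feature-ID order) and, within a
// column, towards the smallest threshold. Each column is sorted once per
// tree; nodes scan the presorted order through a membership mask.

static const double GAIN_TOL = 1e-12;

static double entropy_bits(const std::vector<int> &counts, int total) {
  if (total <= 0) return 0.0;
  double h = 0.0;
  for (size_t c = 0; c < counts.size(); ++c) {
    if (counts[c] > 0) {
      double p = (double)counts[c] / total;
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct NodeRec {
  int feature;      // 1-based column in X, 0 for leaf
  double threshold; // split: x <= threshold goes left
  double ig;        // info gain (bits) or variance reduction
  int n;            // samples reaching the node
  int left, right;  // 1-based node indices, 0 for leaf
  double pred;      // class code (1-based) or mean
};

struct BestSplit {
  int col; // 0-based, -1 = none
  double threshold;
  double gain;
};

// [[Rcpp::export(name = ".cpp_build_tree")]]
List cpp_build_tree(NumericMatrix X, NumericVector y, bool classification,
                    int nclass, int min_split) {
  const int n = X.nrow();
  const int m = X.ncol();

  // presort every column once
  std::vector<std::vector<int>> ord(m, std::vector<int>(n));
  for (int j = 0; j < m; ++j) {
    const double *col = &X(0, j);
    std::vector<int> &oj = ord[j];
    for (int i = 0; i < n; ++i) oj[i] = i;
    std::stable_sort(oj.begin(), oj.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<int> ycls;
  if (classification) {
    ycls.resize(n);
    for (int i = 0; i < n; ++i) ycls[i] = (int)y[i]; // 0-based codes
  }

  std::vector<NodeRec> nodes;
  nodes.reserve(64);
  std::vector<std::pair<int, std::vector<int>>> stack;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  nodes.push_back(NodeRec{0, NA_REAL, 0.0, n, 0, 0, NA_REAL});
  stack.push_back(std::make_pair(0, all));

  std::vector<char> in_node(n, 0);
  std::vector<double> vals(n), yy(n);
  std::vector<int> cls(n);
  std::vector<int> left_cnt(classification ? nclass : 0),
      right_cnt(classification ? nclass : 0);
  std::vector<double> ltab(n + 1, 0.0); // k * log2(k)
  for (int k = 2; k <= n; ++k) ltab[k] = k * std::log2((double)k);

  while (!stack.empty()) {
    int ni = stack.back().first;
    std::vector<int> idx = std::move(stack.back().second);
    stack.pop_back();
    int nn = (int)idx.size();
    nodes[ni].n = nn;

    bool make_leaf = false;
    double parent_stat = 0.0;

    if (classification) {
      std::vector<int> cnt(nclass, 0);
      for (int i = 0; i < nn; ++i) cnt[ycls[idx[i]]]++;
      int best_c = 0;
      for (int c = 1; c < nclass; ++c)
        if (cnt[c] > cnt[best_c]) best_c = c; // ties -> smaller class code
      nodes[ni].pred = best_c + 1.0;
      parent_stat = entropy_bits(cnt, nn);
      if (nn < min_split || parent_stat <= 0.0) make_leaf = true;
    } else {
      double s = 0.0, ss = 0.0;
      for (int i = 0; i < nn; ++i) {
        s += y[idx[i]];
        ss += y[idx[i]] * y[idx[i]];
      }
      double mu = s / nn;
      nodes[ni].pred = mu;
      parent_stat = ss / nn - mu * mu;
      if (parent_stat < 0) parent_stat = 0;
      if (nn < min_split || parent_stat <= GAIN_TOL) make_leaf = true;
    }

    BestSplit best = {-1, 0.0, 0.0};
    if (!make_leaf) {
      for (int i = 0; i < nn; ++i) in_node[idx[i]] = 1;
      for (int j = 0; j < m; ++j) {
        const double *col = &X(0, j);
        const std::vector<int> &oj = ord[j];
        int k = 0;
        if (classification) {
          for (int i = 0; i < n; ++i) {
            int r = oj[i];
            if (in_node[r]) {
              vals[k] = col[r];
              cls[k] = ycls[r];
              ++k;
            }
          }
          std::fill(left_cnt.begin(), left_cnt.end(), 0);
          std::fill(right_cnt.begin(), right_cnt.end(), 0);
          for (int i = 0; i < nn; ++i) right_cnt[cls[i]]++;
          // incremental weighted child entropy via the k*log2(k) table:
          // (nl/nn)*H_l = (L[nl] - sum_c L[cnt_lc]) / nn
          double sum_l = 0.0, sum_r = 0.0;
          for (int c = 0; c < nclass; ++c) sum_r += ltab[right_cnt[c]];
          for (int i = 0; i < nn - 1; ++i) {
            int c = cls[i];
            sum_l += ltab[left_cnt[c] + 1] - ltab[left_cnt[c]];
            sum_r += ltab[right_cnt[c] - 1] - ltab[right_cnt[c]];
            left_cnt[c]++;
            right_cnt[c]--;
            if (vals[i + 1] <= vals[i]) continue;
            int nl = i + 1, nr = nn - nl;
            double h =
                (ltab[nl] - sum_l + ltab[nr] - sum_r) / nn;
            double gain = parent_stat - h;
            if (gain > best.gain + GAIN_TOL) {
              best.col = j;
              best.threshold = 0.5 * (vals[i] + vals[i + 1]);
              best.gain = gain;
            }
          }
        } else {
          for (int i = 0; i < n; ++i) {
            int r = oj[i];
            if (in_node[r]) {
              vals[k] = col[r];
              yy[k] = y[r];
              ++k;
            }
          }
          double s_tot = 0.0, ss_tot = 0.0;
          for (int i = 0; i < nn; ++i) {
            s_tot += yy[i];
            ss_tot += yy[i] * yy[i];
          }
          double s_l = 0.0, ss_l = 0.0;
          for (int i = 0; i < nn - 1; ++i) {
            s_l += yy[i];
            ss_l += yy[i] * yy[i];
            if (vals[i + 1] <= vals[i]) continue;
            int nl = i + 1, nr = nn - nl;
            double s_r = s_tot - s_l, ss_r = ss_tot - ss_l;
            double var_l = ss_l / nl - (s_l / nl) * (s_l / nl);
            double var_r = ss_r / nr - (s_r / nr) * (s_r / nr);
            double gain = parent_stat - ((double)nl / nn) * var_l -
                          ((double)nr / nn) * var_r;
            if (gain > best.gain + GAIN_TOL) {
              best.col = j;
              best.threshold = 0.5 * (vals[i] + vals[i + 1]);
              best.gain = gain;
            }
          }
        }
      }
      for (int i = 0; i < nn; ++i) in_node[idx[i]] = 0;
      if (best.col < 0 || best.gain <= GAIN_TOL) make_leaf = true;
    }
    if (make_leaf) continue;

    std::vector<int> li, ri;
    li.reserve(nn);
    ri.reserve(nn);
    for (int i = 0; i < nn; ++i) {
      if (X(idx[i], best.col) <= best.threshold) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    nodes[ni].feature = best.col + 1;
    nodes[ni].threshold = best.threshold;
    nodes[ni].ig = best.gain;
    int l = (int)nodes.size();
    nodes.push_back(NodeRec{0, NA_REAL, 0.0, (int)li.size(), 0, 0, NA_REAL});
    int r = (int)nodes.size();
    nodes.push_back(NodeRec{0, NA_REAL, 0.0, (int)ri.size(), 0, 0, NA_REAL});
    nodes[ni].left = l + 1;
    nodes[ni].right = r + 1;
    stack.push_back(std::make_pair(r, std::move(ri)));
    stack.push_back(std::make_pair(l, std::move(li)));
  }

  int sz = (int)nodes.size();
  IntegerVector feature(sz), nvec(sz), left(sz), right(sz);
  NumericVector threshold(sz), ig(sz), pred(sz);
  for (int i = 0; i < sz; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    ig[i] = nodes[i].ig;
    nvec[i] = nodes[i].n;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["ig"] = ig, _["n"] = nvec, _["left"] = left,
                      _["right"] = right, _["pred"] = pred);
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector pred, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] > 0) {
      if (X(i, feature[node] - 1) <= threshold[node]) node = left[node] - 1;
      else node = right[node] - 1;
    }
    out[i] = pred[node];
  }
  return out;
}
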