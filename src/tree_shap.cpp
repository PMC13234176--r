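#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Interventional Shapley attribution for a forest of binary trees.
//
// For one foreground row x and one background row z, the model restricted to
// a coalition S takes x's values on features in S and z's values elsewhere.
// A root-to-leaf path is reachable under S iff every split where x and z
// disagree in direction is resolved consistently: features forced to x's
// branch form the "present" set P, features forced to z's branch the
// "absent" set A. The induced game v(S) = leaf_value * 1[P subset S, A
// disjoint S] has closed-form Shapley values depending only on |P| and |A|:
//   i in P:  +v * (|P|-1)! |A)! / (|P|+|A|)!
//   i in A:  -v * |P|! (|A|-1)! / (|P|+|A|)!
// Summing over leaves, trees and backgrounds gives exact interventional
// Shapley values of the forest against the background distribution.
//
// Node convention (matching ranger::treeInfo): a sample goes left when
// x[feat] <= thresh. Leaves have feat == -1 and carry the class-1
// probability in `value`. Node indices are absolute into the flat arrays;
// `roots` holds each tree's root index.

static const int MAX_PATH = 128;

struct ShapCtx {
  const int *left, *right, *feat;
  const double *thresh, *value;
  const unsigned char *live;    // node has a nonzero leaf below it
  const double *x, *z;          // single rows, stride = 1 (copied)
  double *phi;                  // length p accumulator
  const double *wpos, *wneg;    // [(p_cnt)*(MAX_PATH) + a_cnt] weight tables
  int pset[MAX_PATH], aset[MAX_PATH];
  uint64_t pmask, amask;        // fast membership when p <= 64
  int pcnt, acnt;
  bool use_mask;
};

static void shap_recurse(ShapCtx &c, int node) {
  if (!c.live[node]) return; // every leaf below is zero-valued
  int f = c.feat[node];
  if (f < 0) { // leaf
    double v = c.value[node];
    if (c.pcnt > 0) {
      double w = v * c.wpos[c.pcnt * MAX_PATH + c.acnt];
      for (int i = 0; i < c.pcnt; ++i) c.phi[c.pset[i]] += w;
    }
    if (c.acnt > 0) {
      double w = v * c.wneg[c.pcnt * MAX_PATH + c.acnt];
      for (int i = 0; i < c.acnt; ++i) c.phi[c.aset[i]] -= w;
    }
    return;
  }
  bool xleft = c.x[f] <= c.thresh[node];
  bool zleft = c.z[f] <= c.thresh[node];
  // a feature already committed to one side must stay there
  if (c.use_mask) {
    uint64_t bit = 1ULL << f;
    if (c.pmask & bit) { shap_recurse(c, xleft ? c.left[node] : c.right[node]); return; }
    if (c.amask & bit) { shap_recurse(c, zleft ? c.left[node] : c.right[node]); return; }
  } else {
    for (int i = 0; i < c.pcnt; ++i) {
      if (c.pset[i] == f) { shap_recurse(c, xleft ? c.left[node] : c.right[node]); return; }
    }
    for (int i = 0; i < c.acnt; ++i) {
      if (c.aset[i] == f) { shap_recurse(c, zleft ? c.left[node] : c.right[node]); return; }
    }
  }
  if (xleft == zleft) {
    shap_recurse(c, xleft ? c.left[node] : c.right[node]);
    return;
  }
  if (c.pcnt >= MAX_PATH || c.acnt >= MAX_PATH) Rcpp::stop("tree path too deep");
  uint64_t bit = c.use_mask ? (1ULL << f) : 0;
  c.pset[c.pcnt++] = f; c.pmask |= bit;
  shap_recurse(c, xleft ? c.left[node] : c.right[node]);
  c.pcnt--; c.pmask &= ~bit;
  c.aset[c.acnt++] = f; c.amask |= bit;
  shap_recurse(c, zleft ? c.left[node] : c.right[node]);
  c.acnt--; c.amask &= ~bit;
}

// [[Rcpp::export]]
NumericMatrix tree_shap_interventional_cpp(IntegerVector roots,
                                           IntegerVector left,
                                           IntegerVector right,
                                           IntegerVector feat,
                                           NumericVector thresh,
                                           NumericVector value,
                                           NumericMatrix X,
                                           NumericMatrix Z) {
  const int n = X.nrow(), p = X.ncol(), m = Z.nrow(), T = roots.size();
  if (Z.ncol() != p) stop("foreground and background must share columns");
  if (m == 0) stop("background set is empty");

  // factorial weight tables indexed [pcnt * MAX_PATH + acnt]
  std::vector<double> wpos(MAX_PATH * MAX_PATH, 0.0), wneg(MAX_PATH * MAX_PATH, 0.0);
  for (int pc = 0; pc < MAX_PATH; ++pc) {
    for (int ac = 0; ac + pc < MAX_PATH; ++ac) {
      if (pc > 0)
        wpos[pc * MAX_PATH + ac] = std::exp(std::lgamma(pc) + std::lgamma(ac + 1.0)
                                            - std::lgamma(pc + ac + 1.0));
      if (ac > 0)
        wneg[pc * MAX_PATH + ac] = std::exp(std::lgamma(pc + 1.0) + std::lgamma((double)ac)
                                            - std::lgamma(pc + ac + 1.0));
    }
  }

  // mark nodes with at least one nonzero leaf below (others cannot
  // contribute and are pruned); node arrays are child-after-parent, so a
  // reverse sweep propagates the flag upward
  const int n_nodes = left.size();
  std::vector<unsigned char> live(n_nodes, 0);
  for (int v = n_nodes - 1; v >= 0; --v) {
    if (feat[v] < 0) live[v] = value[v] != 0.0;
    else live[v] = live[left[v]] || live[right[v]];
  }

  NumericMatrix phi(n, p);
  std::vector<double> xrow(p), zrow(p), acc(p);
  ShapCtx c;
  c.left = left.begin(); c.right = right.begin(); c.feat = feat.begin();
  c.thresh = thresh.begin(); c.value = value.begin();
  c.live = live.data();
  c.wpos = wpos.data(); c.wneg = wneg.data();
  c.x = xrow.data(); c.z = zrow.data(); c.phi = acc.data();
  c.use_mask = (p <= 64);
  c.pmask = 0; c.amask = 0;

  const double denom = (double)m * (double)T;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int b = 0; b < m; ++b) {
      for (int j = 0; j < p; ++j) zrow[j] = Z(b, j);
      for (int t = 0; t < T; ++t) {
        c.pcnt = 0; c.acnt = 0;
        shap_recurse(c, roots[t]);
      }
    }
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j] / denom;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return phi;
}

// Predict class-1 probability with the flattened forest (used to validate the
// node-layout convention against ranger's own predictions).
// [[Rcpp::export]]
NumericVector flat_forest_predict_cpp(IntegerVector roots,
                                      IntegerVector left,
                                      IntegerVector right,
                                      IntegerVector feat,
                                      NumericVector thresh,
                                      NumericVector value,
                                      NumericMatrix X) {
  const int n = X.nrow(), T = roots.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      int node = roots[t];
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thresh[node]) ? left[node] : right[node];
      }
      s += value[node];
    }
    out[i] = s / T;
  }
  return out;
}
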