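#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Feature- and sample-weighted random forest for binary outcomes.
//
// Each split draws `mtry` candidate features WITH replacement with
// probability proportional to the feature weights (duplicates collapse),
// then takes the best weighted-Gini split among the candidates. With
// uniform weights this is ordinary random-forest candidate sampling; with
// sharply peaked weights the candidate set collapses onto the
// highest-weight features, realizing the soft feature selection that
// feature weighting requires. Zero-weight features can never be drawn.
// Sample weights enter impurity, leaf values and the minimum-leaf-weight
// constraint; bootstrap multiplicities are folded into the weights (exact,
// since every statistic is weight-linear).
//
// All randomness comes from the raw mt19937_64 stream (no std::
// distributions, whose mappings are implementation-defined), so fits are
// bit-reproducible across platforms for a given seed.

namespace {

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return std::min((int)(unif() * n), n - 1); }
};

struct Builder {
  const double* X; // column-major n x p (full training matrix)
  int n, p;
  std::vector<int> rows;    // aggregated bootstrap: distinct row ids
  std::vector<double> wts;  // multiplicity * sample weight per entry
  std::vector<double> wy;   // wts * y per entry
  std::vector<double> fw_cum;
  int mtry;
  double min_leaf_w;
  int max_depth;
  Rng rng;
  std::vector<std::pair<double, int>> buf; // (feature value, entry) scratch

  std::vector<int> left, right, feat;
  std::vector<double> thresh, value;

  Builder(const double* X_, int n_, int p_, const double* fw, int mtry_,
          uint64_t seed)
      : X(X_), n(n_), p(p_), mtry(mtry_), min_leaf_w(0), max_depth(100),
        rng(seed) {
    fw_cum.resize(p);
    double acc = 0;
    for (int j = 0; j < p; ++j) { acc += fw[j]; fw_cum[j] = acc; }
    for (int j = 0; j < p; ++j) fw_cum[j] /= acc;
  }

  int draw_feature() {
    double u = 1.0 - rng.unif(); // in (0, 1]: zero-weight features unreachable
    return (int)(std::lower_bound(fw_cum.begin(), fw_cum.end(), u)
                 - fw_cum.begin());
  }

  int new_leaf(double sw, double swy) {
    left.push_back(-1); right.push_back(-1); feat.push_back(-1);
    thresh.push_back(0.0);
    value.push_back(sw > 0 ? swy / sw : 0.5);
    return (int)left.size() - 1;
  }

  int build(std::vector<int>& ent, int depth) {
    double sw = 0, swy = 0;
    for (int e : ent) { sw += wts[e]; swy += wy[e]; }
    bool pure = (swy <= 0) || (swy >= sw);
    if (pure || depth >= max_depth || sw < 2 * min_leaf_w || ent.size() < 2) {
      return new_leaf(sw, swy);
    }

    // candidate multiset: mtry weighted draws with replacement, deduplicated
    int cand[64]; int ncand = 0;
    for (int d = 0; d < mtry && d < 64; ++d) {
      int f = draw_feature();
      bool seen = false;
      for (int q = 0; q < ncand; ++q) if (cand[q] == f) { seen = true; break; }
      if (!seen) cand[ncand++] = f;
    }

    const double parent_imp = 2.0 * (swy / sw) * (1.0 - swy / sw) * sw;
    double best_gain = 1e-12; // require a strictly positive improvement
    int best_f = -1; double best_t = 0;

    for (int c = 0; c < ncand; ++c) {
      int f = cand[c];
      const double* col = X + (size_t)f * n;
      buf.resize(ent.size());
      for (size_t k = 0; k < ent.size(); ++k) {
        buf[k] = {col[rows[ent[k]]], ent[k]};
      }
      std::sort(buf.begin(), buf.end());
      double wl = 0, wly = 0;
      for (size_t k = 0; k + 1 < buf.size(); ++k) {
        int e = buf[k].second;
        wl += wts[e]; wly += wy[e];
        if (buf[k].first == buf[k + 1].first) continue; // not a valid cut
        double wr = sw - wl, wry = swy - wly;
        if (wl < min_leaf_w || wr < min_leaf_w) continue;
        double impl = wl > 0 ? 2.0 * (wly / wl) * (1.0 - wly / wl) * wl : 0;
        double impr = wr > 0 ? 2.0 * (wry / wr) * (1.0 - wry / wr) * wr : 0;
        double gain = parent_imp - impl - impr;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_t = buf[k].first + 0.5 * (buf[k + 1].first - buf[k].first);
        }
      }
    }
    if (best_f < 0) return new_leaf(sw, swy);

    const double* col = X + (size_t)best_f * n;
    std::vector<int> li, ri;
    for (int e : ent) (col[rows[e]] <= best_t ? li : ri).push_back(e);
    if (li.empty() || ri.empty()) return new_leaf(sw, swy);

    int node = (int)left.size();
    left.push_back(0); right.push_back(0); feat.push_back(best_f);
    thresh.push_back(best_t); value.push_back(0.0);
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    left[node] = l; right[node] = r;
    return node;
  }
};

} // namespace

// [[Rcpp::export]]
List weighted_forest_fit_cpp(NumericMatrix X, IntegerVector y,
                             NumericVector sample_w, NumericVector feature_w,
                             int n_trees, int mtry,
                             double min_weight_fraction_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (p > 0 && mtry < 1) stop("mtry must be >= 1");
  std::vector<int> roots_all;
  std::vector<int> left_all, right_all, feat_all;
  std::vector<double> thresh_all, value_all;
  std::vector<int> mult(n);

  for (int t = 0; t < n_trees; ++t) {
    uint64_t ts = (uint64_t)(uint32_t)seed * 2654435761ULL + 97531ULL * (t + 1);
    Rng boot_rng(ts ^ 0x9e3779b97f4a7c15ULL);
    std::fill(mult.begin(), mult.end(), 0);
    for (int i = 0; i < n; ++i) mult[boot_rng.below(n)]++;

    Builder b(X.begin(), n, p, feature_w.begin(), mtry, ts);
    double root_w = 0;
    for (int i = 0; i < n; ++i) {
      if (mult[i] == 0) continue;
      double w = mult[i] * sample_w[i];
      b.rows.push_back(i);
      b.wts.push_back(w);
      b.wy.push_back(w * y[i]);
      root_w += w;
    }
    b.min_leaf_w = min_weight_fraction_leaf * root_w;
    std::vector<int> ent(b.rows.size());
    for (size_t k = 0; k < ent.size(); ++k) ent[k] = (int)k;
    int root = b.build(ent, 0);

    int off = (int)left_all.size();
    roots_all.push_back(root + off);
    for (size_t k = 0; k < b.left.size(); ++k) {
      left_all.push_back(b.left[k] >= 0 ? b.left[k] + off : -1);
      right_all.push_back(b.right[k] >= 0 ? b.right[k] + off : -1);
      feat_all.push_back(b.feat[k]);
      thresh_all.push_back(b.thresh[k]);
      value_all.push_back(b.value[k]);
    }
    if (t % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["roots"] = wrap(roots_all),
                      _["left"] = wrap(left_all),
                      _["right"] = wrap(right_all),
                      _["feat"] = wrap(feat_all),
                      _["thresh"] = wrap(thresh_all),
                      _["value"] = wrap(value_all));
}
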