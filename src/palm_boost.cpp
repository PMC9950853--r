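#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Core tree machinery for the boosted two-groups prior.
//
// Trees are grown level-wise by exact greedy search over all midpoints of
// sorted unique feature values, with XGBoost-style sparsity-aware handling
// of missing values: at every split both routings of the missing rows are
// scored and the gain-maximising one is stored as the default direction.
//
// Conventions: g is the first derivative of the Q-function at f=0
// (q1 - sigmoid(F)), hneg = -h > 0 is the (positive) curvature weight.
// Leaf value is the Newton step  sum(g) / (sum(hneg) + lambda).
// Split gain is 0.5 * [GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)].

static inline double leaf_score(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// [[Rcpp::export]]
List cpp_presort(NumericMatrix A) {
  int M = A.nrow(), L = A.ncol();
  List ord(L), miss(L), vals(L);
  std::vector<int> idx;
  for (int l = 0; l < L; ++l) {
    idx.clear();
    std::vector<int> mi;
    for (int j = 0; j < M; ++j) {
      if (NumericMatrix::is_na(A(j, l)) || std::isnan(A(j, l))) mi.push_back(j);
      else idx.push_back(j);
    }
    const double *col = &A(0, l);
    std::stable_sort(idx.begin(), idx.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
    NumericVector sv(idx.size());
    for (size_t k = 0; k < idx.size(); ++k) sv[k] = col[idx[k]];
    ord[l] = IntegerVector(idx.begin(), idx.end());
    miss[l] = IntegerVector(mi.begin(), mi.end());
    vals[l] = sv;
  }
  return List::create(_["ord"] = ord, _["miss"] = miss, _["vals"] = vals);
}

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix A, List ord, List miss, List vals,
                  NumericVector g, NumericVector hneg,
                  int depth, double min_child_weight, double lambda) {
  const int M = A.nrow(), L = A.ncol();
  if (depth > 6) stop("tree depth > 6 not supported");
  const double GAIN_EPS = 1e-12;
  const double *gp = g.begin(), *hp = hneg.begin();

  // raw views of the presort structure (no per-level re-extraction)
  std::vector<const int *> ordp(L), missp(L);
  std::vector<const double *> valp(L);
  std::vector<int> ordn(L), missn(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector ol = ord[l], ml = miss[l];
    NumericVector vl = vals[l];
    ordp[l] = ol.begin(); ordn[l] = ol.size();
    missp[l] = ml.begin(); missn[l] = ml.size();
    valp[l] = vl.begin();
  }

  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> def_left;     // 1 = missing goes left
  std::vector<int> kid_l, kid_r; // -1 for leaf
  std::vector<double> value, nodeG, nodeH;
  NumericVector gain_vec(L);

  std::vector<int> node_of_row(M, 0);

  double G0 = 0.0, H0 = 0.0;
  for (int j = 0; j < M; ++j) { G0 += g[j]; H0 += hneg[j]; }
  feature.push_back(-1); threshold.push_back(NA_REAL); def_left.push_back(1);
  kid_l.push_back(-1); kid_r.push_back(-1);
  value.push_back(G0 / (H0 + lambda)); nodeG.push_back(G0); nodeH.push_back(H0);

  std::vector<int> level_nodes(1, 0);

  std::vector<signed char> lev_row(M);

  for (int d = 0; d < depth && !level_nodes.empty(); ++d) {
    const int nl = (int)level_nodes.size();
    std::vector<int> lev_of_node(feature.size(), -1);
    for (int i = 0; i < nl; ++i) lev_of_node[level_nodes[i]] = i;
    for (int row = 0; row < M; ++row)
      lev_row[row] = (signed char)lev_of_node[node_of_row[row]];

    std::vector<double> bestGain(nl, GAIN_EPS), bestThr(nl, 0.0);
    std::vector<int> bestFeat(nl, -1), bestMissLeft(nl, 1);
    std::vector<double> bestGL(nl), bestHL(nl);  // left-child stats incl. missing if routed left
    std::vector<double> parent_score(nl);
    std::vector<char> splittable(nl);
    for (int i = 0; i < nl; ++i) {
      int nid = level_nodes[i];
      parent_score[i] = leaf_score(nodeG[nid], nodeH[nid], lambda);
      splittable[i] = (nodeH[nid] >= 2.0 * min_child_weight);
    }

    std::vector<double> Gm(nl), Hm(nl), GL(nl), HL(nl), prevv(nl);
    std::vector<char> hasprev(nl);

    for (int l = 0; l < L; ++l) {
      std::fill(Gm.begin(), Gm.end(), 0.0);
      std::fill(Hm.begin(), Hm.end(), 0.0);
      bool any_miss = false;
      const int *ml = missp[l];
      for (int k = 0; k < missn[l]; ++k) {
        int row = ml[k], li = lev_row[row];
        if (li >= 0) { Gm[li] += gp[row]; Hm[li] += hp[row]; any_miss = true; }
      }
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(hasprev.begin(), hasprev.end(), 0);

      const int *ol = ordp[l];
      const double *sv = valp[l];
      const int n = ordn[l];
      for (int k = 0; k < n; ++k) {
        const int row = ol[k];
        const int li = lev_row[row];
        if (li < 0) continue;
        const double v = sv[k];
        if (hasprev[li] && v > prevv[li] && splittable[li]) {
          const int nid = level_nodes[li];
          const double G = nodeG[nid], H = nodeH[nid];
          const double thr = 0.5 * (prevv[li] + v);
          // missing -> right
          {
            const double gl = GL[li], hl = HL[li];
            const double gr = G - gl, hr = H - hl;
            if (hl >= min_child_weight && hr >= min_child_weight) {
              const double gn = 0.5 * (leaf_score(gl, hl, lambda) +
                                       leaf_score(gr, hr, lambda) -
                                       parent_score[li]);
              if (gn > bestGain[li]) {
                bestGain[li] = gn; bestFeat[li] = l; bestThr[li] = thr;
                bestMissLeft[li] = 1; bestGL[li] = gl; bestHL[li] = hl;
                // with no missing mass both routings tie; default is left
                if (any_miss && (Gm[li] != 0.0 || Hm[li] != 0.0))
                  bestMissLeft[li] = 0;
              }
            }
          }
          // missing -> left (evaluated second; on exact ties left wins via >=)
          if (any_miss && (Gm[li] != 0.0 || Hm[li] != 0.0)) {
            const double gl = GL[li] + Gm[li], hl = HL[li] + Hm[li];
            const double gr = G - gl, hr = H - hl;
            if (hl >= min_child_weight && hr >= min_child_weight) {
              const double gn = 0.5 * (leaf_score(gl, hl, lambda) +
                                       leaf_score(gr, hr, lambda) -
                                       parent_score[li]);
              bool tie_same = (bestFeat[li] == l && bestThr[li] == thr &&
                               gn >= bestGain[li]);
              if (gn > bestGain[li] || tie_same) {
                bestGain[li] = gn; bestFeat[li] = l; bestThr[li] = thr;
                bestMissLeft[li] = 1; bestGL[li] = gl; bestHL[li] = hl;
              }
            }
          }
        }
        GL[li] += gp[row]; HL[li] += hp[row];
        prevv[li] = v; hasprev[li] = 1;
      }
    }

    // materialise accepted splits
    std::vector<int> next_level;
    for (int i = 0; i < nl; ++i) {
      if (bestFeat[i] < 0) continue;
      int nid = level_nodes[i];
      int lc = (int)feature.size(), rc = lc + 1;
      double Gl = bestGL[i], Hl = bestHL[i];
      double Gr = nodeG[nid] - Gl, Hr = nodeH[nid] - Hl;
      feature[nid] = bestFeat[i]; threshold[nid] = bestThr[i];
      def_left[nid] = bestMissLeft[i]; kid_l[nid] = lc; kid_r[nid] = rc;
      gain_vec[bestFeat[i]] += bestGain[i];
      for (int c = 0; c < 2; ++c) {
        feature.push_back(-1); threshold.push_back(NA_REAL); def_left.push_back(1);
        kid_l.push_back(-1); kid_r.push_back(-1);
      }
      value[nid] = NA_REAL;
      value.push_back(Gl / (Hl + lambda)); nodeG.push_back(Gl); nodeH.push_back(Hl);
      value.push_back(Gr / (Hr + lambda)); nodeG.push_back(Gr); nodeH.push_back(Hr);
      next_level.push_back(lc); next_level.push_back(rc);
    }
    if (next_level.empty()) break;

    // re-route rows of split nodes
    for (int row = 0; row < M; ++row) {
      int nid = node_of_row[row];
      int li = lev_of_node[nid];
      if (li < 0 || bestFeat[li] < 0) continue;
      double v = A(row, feature[nid]);
      bool left;
      if (NumericMatrix::is_na(v) || std::isnan(v)) left = def_left[nid];
      else left = (v <= threshold[nid]);
      node_of_row[row] = left ? kid_l[nid] : kid_r[nid];
    }
    level_nodes = next_level;
  }

  return List::create(
    _["feature"] = IntegerVector(feature.begin(), feature.end()),
    _["threshold"] = NumericVector(threshold.begin(), threshold.end()),
    _["default_left"] = IntegerVector(def_left.begin(), def_left.end()),
    _["left"] = IntegerVector(kid_l.begin(), kid_l.end()),
    _["right"] = IntegerVector(kid_r.begin(), kid_r.end()),
    _["value"] = NumericVector(value.begin(), value.end()),
    _["gain"] = gain_vec);
}

static inline double eval_tree(const int *feat, const double *thr,
                               const int *defl, const int *lft, const int *rgt,
                               const double *val, const NumericMatrix &A,
                               int row) {
  int n = 0;
  while (feat[n] >= 0) {
    double v = A(row, feat[n]);
    bool left;
    if (NumericMatrix::is_na(v) || std::isnan(v)) left = defl[n];
    else left = (v <= thr[n]);
    n = left ? lft[n] : rgt[n];
  }
  return val[n];
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix A) {
  IntegerVector feat = tree["feature"], defl = tree["default_left"],
                lft = tree["left"], rgt = tree["right"];
  NumericVector thr = tree["threshold"], val = tree["value"];
  int M = A.nrow();
  NumericVector out(M);
  for (int j = 0; j < M; ++j)
    out[j] = eval_tree(feat.begin(), thr.begin(), defl.begin(), lft.begin(),
                       rgt.begin(), val.begin(), A, j);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_ensemble(List trees, NumericMatrix A,
                                   double f0, double nu, int ntrees) {
  int M = A.nrow();
  NumericVector out(M, f0);
  int T = std::min((int)trees.size(), ntrees);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector feat = tree["feature"], defl = tree["default_left"],
                  lft = tree["left"], rgt = tree["right"];
    NumericVector thr = tree["threshold"], val = tree["value"];
    for (int j = 0; j < M; ++j)
      out[j] += nu * eval_tree(feat.begin(), thr.begin(), defl.begin(),
                               lft.begin(), rgt.begin(), val.begin(), A, j);
  }
  return out;
}

// Tree evaluation with one or two feature values overridden (for partial
// dependence): the overridden feature reads from `ov` instead of A(row, .).
static double eval_tree_override(const int *feat, const double *thr,
                                 const int *defl, const int *lft,
                                 const int *rgt, const double *val,
                                 const NumericMatrix &A, int row,
                                 int f1, double v1, int f2, double v2) {
  int n = 0;
  while (feat[n] >= 0) {
    int f = feat[n];
    double v = (f == f1) ? v1 : (f == f2) ? v2 : A(row, f);
    bool left;
    if (ISNAN(v)) left = defl[n];
    else left = (v <= thr[n]);
    n = left ? lft[n] : rgt[n];
  }
  return val[n];
}

// Friedman-Popescu two-variable H^2 for an ensemble over the empirical
// distribution of the remaining annotations. Evaluation points are the n
// rows of A themselves; partial dependences average over the same n rows.
// Trees that split on neither l1 nor l2 contribute only constants to every
// centred partial dependence and are skipped exactly; trees splitting on
// only one of the pair cancel between PD12 and the matching PD1/PD2 and are
// included in both so the cancellation is numerically explicit except for
// the both-feature set, which makes depth-1 ensembles return exactly 0.
// [[Rcpp::export]]
double cpp_h_statistic(List trees, NumericMatrix A, int l1, int l2) {
  int n = A.nrow(), T = trees.size();
  std::vector<char> u1(T, 0), u2(T, 0);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector feat = tree["feature"];
    for (int k = 0; k < feat.size(); ++k) {
      if (feat[k] == l1) u1[t] = 1;
      if (feat[k] == l2) u2[t] = 1;
    }
  }
  // pd12: joint partial dependence over all trees touching the pair;
  // dd: per-point interaction residual PD12 - PD1 - PD2 accumulated only
  // over trees splitting on BOTH features (single-feature trees cancel in
  // the residual identically, so excluding them is exact and keeps additive
  // ensembles at H == 0 to the last bit).
  std::vector<double> pd12(n, 0.0), dd(n, 0.0);
  for (int t = 0; t < T; ++t) {
    if (!u1[t] && !u2[t]) continue;
    List tree = trees[t];
    IntegerVector feat = tree["feature"], defl = tree["default_left"],
                  lft = tree["left"], rgt = tree["right"];
    NumericVector thr = tree["threshold"], val = tree["value"];
    const int *fp = feat.begin(), *dp = defl.begin(), *lp = lft.begin(),
              *rp = rgt.begin();
    const double *tp = thr.begin(), *vp = val.begin();
    const bool both = u1[t] && u2[t];
    for (int j = 0; j < n; ++j) {
      double a1 = A(j, l1), a2 = A(j, l2);
      double s12 = 0.0, s1 = 0.0, s2 = 0.0;
      for (int k = 0; k < n; ++k) {
        if (both)
          s12 += eval_tree_override(fp, tp, dp, lp, rp, vp, A, k, l1, a1, l2, a2);
        if (u1[t]) s1 += eval_tree_override(fp, tp, dp, lp, rp, vp, A, k,
                                            l1, a1, -1, 0.0);
        if (u2[t]) s2 += eval_tree_override(fp, tp, dp, lp, rp, vp, A, k,
                                            l2, a2, -1, 0.0);
      }
      // a tree using exactly one of the pair has PD12 == its own PD1/PD2
      if (both) {
        pd12[j] += s12 / n;
        dd[j] += (s12 - s1 - s2) / n;
      } else if (u1[t]) pd12[j] += s1 / n;
      else pd12[j] += s2 / n;
    }
  }
  double m12 = 0, md = 0;
  for (int j = 0; j < n; ++j) { m12 += pd12[j]; md += dd[j]; }
  m12 /= n; md /= n;
  double num = 0.0, den = 0.0;
  for (int j = 0; j < n; ++j) {
    double c12 = pd12[j] - m12;
    double d = dd[j] - md;
    num += d * d;
    den += c12 * c12;
  }
  if (den <= 0.0) return num > 0.0 ? -1.0 : 0.0;  // -1: caller warns
  double h = num / den;
  if (h < 0.0) h = 0.0;
  if (h > 1.0) h = 1.0;
  return h;
}
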