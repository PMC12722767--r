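// Gradient-boosted decision trees with native missing-value routing
// (learned default directions), histogram-based split finding, Newton leaf
// weights with L2 regularization, exact TreeSHAP attribution, and
// rolling-window summary statistics used by the feature extractor.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int kMaxBins = 63;
static const uint8_t kNaBin = 255;
static const double kGammaMin = 1e-9;

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> def_left;  // 1 if NA goes left
  std::vector<int> left, right;
  std::vector<double> value;  // leaf value (shrinkage folded in)
  std::vector<double> cover;  // training sample count
};

struct BinnedData {
  int n, p;
  std::vector<uint8_t> codes;           // n * p, column-major
  std::vector<std::vector<double>> edges;  // per feature: upper bin edges
  uint8_t code(int i, int f) const { return codes[(size_t)f * n + i]; }
};

// quantile-based binning; edges[k] = upper boundary of bin k (midpoint
// between adjacent distinct values), so "x <= edges[k]" sends x left.
static BinnedData bin_data(const NumericMatrix& X) {
  BinnedData bd;
  bd.n = X.nrow(); bd.p = X.ncol();
  bd.codes.resize((size_t)bd.n * bd.p);
  bd.edges.resize(bd.p);
  std::vector<double> vals;
  for (int f = 0; f < bd.p; ++f) {
    vals.clear();
    for (int i = 0; i < bd.n; ++i)
      if (!ISNAN(X(i, f))) vals.push_back(X(i, f));
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    std::vector<double>& e = bd.edges[f];
    if ((int)vals.size() <= kMaxBins) {
      for (size_t k = 0; k + 1 < vals.size(); ++k)
        e.push_back(0.5 * (vals[k] + vals[k + 1]));
    } else {
      for (int k = 1; k < kMaxBins; ++k) {
        size_t idx = (size_t)((double)k / kMaxBins * vals.size());
        idx = std::min(idx, vals.size() - 2);
        double cand = 0.5 * (vals[idx] + vals[idx + 1]);
        if (e.empty() || cand > e.back()) e.push_back(cand);
      }
    }
    for (int i = 0; i < bd.n; ++i) {
      double v = X(i, f);
      uint8_t c;
      if (ISNAN(v)) c = kNaBin;
      else c = (uint8_t)(std::upper_bound(e.begin(), e.end(), v) - e.begin());
      bd.codes[(size_t)f * bd.n + i] = c;
    }
  }
  return bd;
}

struct SplitInfo {
  int feat = -1;
  int bin = -1;      // go left iff code <= bin (plus NA if def_left)
  bool def_left = false;
  double gain = 0.0;
};

static SplitInfo best_split_hist(const BinnedData& bd,
                                 const std::vector<double>& g,
                                 const std::vector<double>& h,
                                 const std::vector<int>& idx, double lambda,
                                 int min_leaf) {
  SplitInfo best;
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  const double parent = G * G / (H + lambda);
  std::vector<double> hg(kMaxBins + 1), hh(kMaxBins + 1);
  std::vector<int> hc(kMaxBins + 1);
  for (int f = 0; f < bd.p; ++f) {
    const int nb = (int)bd.edges[f].size() + 1;
    if (nb < 2) continue;
    std::fill(hg.begin(), hg.begin() + nb, 0.0);
    std::fill(hh.begin(), hh.begin() + nb, 0.0);
    std::fill(hc.begin(), hc.begin() + nb, 0);
    double Gna = 0, Hna = 0;
    int n_na = 0;
    for (int i : idx) {
      uint8_t c = bd.code(i, f);
      if (c == kNaBin) { Gna += g[i]; Hna += h[i]; ++n_na; }
      else { hg[c] += g[i]; hh[c] += h[i]; ++hc[c]; }
    }
    double GL = 0, HL = 0;
    int nL = 0;
    const int n_obs = (int)idx.size() - n_na;
    for (int b = 0; b + 1 < nb; ++b) {
      GL += hg[b]; HL += hh[b]; nL += hc[b];
      // NA right
      {
        int cl = nL, cr = (n_obs - nL) + n_na;
        if (cl >= min_leaf && cr >= min_leaf) {
          double GR = G - GL, HR = H - HL;
          double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent;
          if (gain > best.gain + kGammaMin) best = {f, b, false, gain};
        }
      }
      // NA left
      if (n_na > 0) {
        int cl = nL + n_na, cr = n_obs - nL;
        if (cl >= min_leaf && cr >= min_leaf) {
          double GLa = GL + Gna, HLa = HL + Hna;
          double GR = G - GLa, HR = H - HLa;
          double gain = GLa * GLa / (HLa + lambda) + GR * GR / (HR + lambda) - parent;
          if (gain > best.gain + kGammaMin) best = {f, b, true, gain};
        }
      }
    }
  }
  return best;
}

static int grow(Tree& tr, const BinnedData& bd, const std::vector<double>& g,
                const std::vector<double>& h, std::vector<int>& idx, int depth,
                int max_depth, double lambda, int min_leaf, double lr) {
  int id = (int)tr.feat.size();
  tr.feat.push_back(-1); tr.thr.push_back(0); tr.def_left.push_back(0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(0); tr.cover.push_back((double)idx.size());
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  SplitInfo sp;
  if (depth < max_depth && (int)idx.size() >= 2 * min_leaf)
    sp = best_split_hist(bd, g, h, idx, lambda, min_leaf);
  if (sp.feat < 0 || sp.gain <= kGammaMin) {
    tr.value[id] = -lr * G / (H + lambda);
    return id;
  }
  std::vector<int> li, ri;
  for (int i : idx) {
    uint8_t c = bd.code(i, sp.feat);
    bool go_left = (c == kNaBin) ? sp.def_left : (c <= sp.bin);
    (go_left ? li : ri).push_back(i);
  }
  tr.feat[id] = sp.feat;
  tr.thr[id] = bd.edges[sp.feat][sp.bin];
  tr.def_left[id] = sp.def_left;
  int l = grow(tr, bd, g, h, li, depth + 1, max_depth, lambda, min_leaf, lr);
  int r = grow(tr, bd, g, h, ri, depth + 1, max_depth, lambda, min_leaf, lr);
  tr.left[id] = l; tr.right[id] = r;
  return id;
}

static double predict_one(const Tree& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr.feat[node] >= 0) {
    double v = X(row, tr.feat[node]);
    bool go_left = ISNAN(v) ? (tr.def_left[node] != 0) : (v <= tr.thr[node]);
    node = go_left ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

static List tree_to_list(const Tree& tr) {
  return List::create(
    _["feat"] = IntegerVector(tr.feat.begin(), tr.feat.end()),
    _["thr"] = NumericVector(tr.thr.begin(), tr.thr.end()),
    _["def_left"] = IntegerVector(tr.def_left.begin(), tr.def_left.end()),
    _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
    _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
    _["value"] = NumericVector(tr.value.begin(), tr.value.end()),
    _["cover"] = NumericVector(tr.cover.begin(), tr.cover.end()));
}

static Tree tree_from_list(const List& l) {
  Tree tr;
  IntegerVector fe = l["feat"], dl = l["def_left"], le = l["left"], ri = l["right"];
  NumericVector th = l["thr"], va = l["value"], co = l["cover"];
  tr.feat.assign(fe.begin(), fe.end());
  tr.thr.assign(th.begin(), th.end());
  tr.def_left.assign(dl.begin(), dl.end());
  tr.left.assign(le.begin(), le.end());
  tr.right.assign(ri.begin(), ri.end());
  tr.value.assign(va.begin(), va.end());
  tr.cover.assign(co.begin(), co.end());
  return tr;
}

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, std::string objective,
                   int nrounds, double learning_rate, int max_depth,
                   int min_leaf, double lambda, double base_score,
                   NumericMatrix Xval) {
  const int n = X.nrow();
  const int nval = Xval.nrow();
  BinnedData bd = bin_data(X);
  std::vector<double> F(n, base_score), Fval(nval, base_score);
  std::vector<double> g(n), h(n);
  List trees(nrounds);
  NumericMatrix val_margins(nval, nrounds);
  for (int round = 0; round < nrounds; ++round) {
    if (objective == "binary") {
      for (int i = 0; i < n; ++i) {
        double p = 1.0 / (1.0 + std::exp(-F[i]));
        g[i] = p - y[i];
        h[i] = std::max(p * (1 - p), 1e-6);
      }
    } else {
      for (int i = 0; i < n; ++i) { g[i] = F[i] - y[i]; h[i] = 1.0; }
    }
    Tree tr;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    grow(tr, bd, g, h, idx, 0, max_depth, lambda, min_leaf, learning_rate);
    for (int i = 0; i < n; ++i) F[i] += predict_one(tr, X, i);
    for (int i = 0; i < nval; ++i) {
      Fval[i] += predict_one(tr, Xval, i);
      val_margins(i, round) = Fval[i];
    }
    trees[round] = tree_to_list(tr);
  }
  return List::create(_["trees"] = trees, _["val_margins"] = val_margins);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, NumericMatrix X, double base_score,
                              int nrounds) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  int use = std::min((int)trees.size(), nrounds);
  for (int t = 0; t < use; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(tr, X, i);
  }
  return out;
}

// ---------------- TreeSHAP (consistent, polynomial-time attribution) ------

struct PathElem {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElem>& path, double pz, double po,
                        int pi) {
  path.push_back({pi, pz, po, path.empty() ? 1.0 : 0.0});
  int l = (int)path.size() - 1;
  for (int i = l - 1; i >= 0; --i) {
    path[i + 1].pweight += po * path[i].pweight * (i + 1) / (double)(l + 1);
    path[i].pweight = pz * path[i].pweight * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PathElem>& path, int i) {
  int l = (int)path.size() - 1;
  double n = path[l].pweight;
  for (int j = l - 1; j >= 0; --j) {
    if (path[i].one_fraction != 0) {
      double tmp = path[j].pweight;
      path[j].pweight = n * (l + 1) / ((j + 1) * path[i].one_fraction);
      n = tmp - path[j].pweight * path[i].zero_fraction * (l - j) / (double)(l + 1);
    } else {
      path[j].pweight = path[j].pweight * (l + 1) /
        (path[i].zero_fraction * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    path[j].feature_index = path[j + 1].feature_index;
    path[j].zero_fraction = path[j + 1].zero_fraction;
    path[j].one_fraction = path[j + 1].one_fraction;
  }
  path.pop_back();
}

static double unwound_sum(const std::vector<PathElem>& path, int i) {
  int l = (int)path.size() - 1;
  double total = 0, n = path[l].pweight;
  for (int j = l - 1; j >= 0; --j) {
    if (path[i].one_fraction != 0) {
      double t = n * (l + 1) / ((j + 1) * path[i].one_fraction);
      total += t;
      n = path[j].pweight - t * path[i].zero_fraction * (l - j) / (double)(l + 1);
    } else {
      total += path[j].pweight * (l + 1) / (path[i].zero_fraction * (l - j));
    }
  }
  return total;
}

static void shap_recurse(const Tree& tr, const NumericMatrix& X, int row,
                         std::vector<double>& phi, int node,
                         std::vector<PathElem> path, double pz, double po,
                         int pi) {
  extend_path(path, pz, po, pi);
  if (tr.feat[node] < 0) {
    int l = (int)path.size() - 1;
    for (int i = 1; i <= l; ++i) {
      double w = unwound_sum(path, i);
      phi[path[i].feature_index] +=
        w * (path[i].one_fraction - path[i].zero_fraction) * tr.value[node];
    }
    return;
  }
  int f = tr.feat[node];
  double v = X(row, f);
  bool go_left = ISNAN(v) ? (tr.def_left[node] != 0) : (v <= tr.thr[node]);
  int hot = go_left ? tr.left[node] : tr.right[node];
  int cold = go_left ? tr.right[node] : tr.left[node];
  double iz = 1, io = 1;
  int k = -1;
  for (int i = 1; i < (int)path.size(); ++i)
    if (path[i].feature_index == f) { k = i; break; }
  if (k >= 0) {
    iz = path[k].zero_fraction;
    io = path[k].one_fraction;
    unwind_path(path, k);
  }
  double cover = tr.cover[node];
  shap_recurse(tr, X, row, phi, hot, path,
               iz * tr.cover[hot] / cover, io, f);
  shap_recurse(tr, X, row, phi, cold, path,
               iz * tr.cover[cold] / cover, 0.0, f);
}

static double tree_mean(const Tree& tr, int node) {
  if (tr.feat[node] < 0) return tr.value[node];
  double c = tr.cover[node];
  return (tr.cover[tr.left[node]] * tree_mean(tr, tr.left[node]) +
          tr.cover[tr.right[node]] * tree_mean(tr, tr.right[node])) / c;
}

// [[Rcpp::export(name = ".gbt_shap_cpp")]]
List gbt_shap_cpp(List trees, NumericMatrix X, double base_score) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double base = base_score;
  std::vector<Tree> trs;
  for (int t = 0; t < trees.size(); ++t)
    trs.push_back(tree_from_list(trees[t]));
  for (const Tree& tr : trs) base += tree_mean(tr, 0);
  for (int i = 0; i < n; ++i) {
    std::vector<double> ph(p, 0.0);
    for (const Tree& tr : trs) {
      std::vector<PathElem> path;
      shap_recurse(tr, X, i, ph, 0, path, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = ph[j];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// ---------------- Rolling trailing-window summaries ------------------------

// type-7 quantile via nth_element (buffer is scrambled, not fully sorted)
static double quantile7(std::vector<double>& v, double q) {
  int n = (int)v.size();
  if (n == 1) return v[0];
  double hidx = (n - 1) * q;
  int lo = (int)std::floor(hidx);
  std::nth_element(v.begin(), v.begin() + lo, v.end());
  double vlo = v[lo];
  if (hidx == lo) return vlo;
  double vhi = *std::min_element(v.begin() + lo + 1, v.end());
  return vlo + (hidx - lo) * (vhi - vlo);
}

// Trailing-window median / IQR / OLS-slope per requested bin (1-based bins).
// Window covers bins [t - w + 1, t], clipped at series start; NAs skipped.
// [[Rcpp::export(name = ".roll_summaries_cpp")]]
NumericMatrix roll_summaries_cpp(NumericVector x, int w, IntegerVector bins) {
  const int m = bins.size();
  NumericMatrix out(m, 3);
  std::vector<double> buf, tt, s;
  for (int bi = 0; bi < m; ++bi) {
    int t = bins[bi] - 1;
    int lo = std::max(0, t - w + 1);
    buf.clear(); tt.clear();
    for (int j = lo; j <= t; ++j) {
      if (!ISNAN(x[j])) { buf.push_back(x[j]); tt.push_back((double)j); }
    }
    if (buf.empty()) {
      out(bi, 0) = NA_REAL; out(bi, 1) = NA_REAL; out(bi, 2) = NA_REAL;
      continue;
    }
    s = buf;
    out(bi, 0) = quantile7(s, 0.5);
    s = buf;
    double q75 = quantile7(s, 0.75);
    s = buf;
    out(bi, 1) = q75 - quantile7(s, 0.25);
    int n = (int)buf.size();
    if (n < 2) { out(bi, 2) = 0.0; continue; }
    double mt = 0, mv = 0;
    for (int k = 0; k < n; ++k) { mt += tt[k]; mv += buf[k]; }
    mt /= n; mv /= n;
    double sxy = 0, sxx = 0;
    for (int k = 0; k < n; ++k) {
      sxy += (tt[k] - mt) * (buf[k] - mv);
      sxx += (tt[k] - mt) * (tt[k] - mt);
    }
    out(bi, 2) = sxx > 0 ? sxy / sxx : 0.0;
  }
  return out;
}
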