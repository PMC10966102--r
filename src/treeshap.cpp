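#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact path-dependent TreeSHAP (Lundberg et al.'s polynomial-time algorithm)
// over a forest given as flat node arrays, computed in double precision.
// Node encoding: feature[i] == -1 marks a leaf; `yes` is taken when
// (float)x < (float)threshold, mirroring the single-precision comparison of
// the boosting library that grew the trees.

struct PathElem {
  int d;        // feature index of the split that created this path element
  double z;     // fraction of "zero" (not conditioned) paths that flow through
  double o;     // fraction of "one" (conditioned) paths that flow through
  double w;     // permutation weight
};

typedef std::vector<PathElem> Path;

static void extend_path(Path &m, double pz, double po, int pi) {
  int l = (int)m.size();
  PathElem e;
  e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1.0) / (l + 1.0);
    m[i].w = pz * m[i].w * (l - i) / (l + 1.0);
  }
}

static void unwind_path(Path &m, int i) {
  int l = (int)m.size() - 1;
  double n = m[l].w;
  if (m[i].o != 0.0) {
    for (int j = l - 1; j >= 0; --j) {
      double t = m[j].w;
      m[j].w = n * (l + 1.0) / ((j + 1.0) * m[i].o);
      n = t - m[j].w * m[i].z * (l - j) / (l + 1.0);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      m[j].w = (m[j].w * (l + 1.0)) / (m[i].z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d; m[j].z = m[j + 1].z; m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_sum(const Path &m, int i) {
  Path cp = m;
  unwind_path(cp, i);
  double s = 0.0;
  for (size_t j = 0; j < cp.size(); ++j) s += cp[j].w;
  return s;
}

struct Forest {
  const IntegerVector &feature;
  const NumericVector &threshold;
  const IntegerVector &yes;
  const IntegerVector &no;
  const NumericVector &value;
  const NumericVector &cover;
};

static void tree_shap_recurse(const Forest &f, const double *x, double *phi,
                              int j, Path m, double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (f.feature[j] < 0) {
    for (int i = 1; i < (int)m.size(); ++i) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * f.value[j];
    }
    return;
  }
  int split_feat = f.feature[j];
  bool go_yes = (float)x[split_feat] < (float)f.threshold[j];
  int hot = go_yes ? f.yes[j] : f.no[j];
  int cold = go_yes ? f.no[j] : f.yes[j];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) {
    if (m[i].d == split_feat) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    unwind_path(m, k);
  }
  tree_shap_recurse(f, x, phi, hot, m,
                    iz * f.cover[hot] / f.cover[j], io, split_feat);
  tree_shap_recurse(f, x, phi, cold, m,
                    iz * f.cover[cold] / f.cover[j], 0.0, split_feat);
}

// expected value of one tree under the cover (training) distribution
static double tree_expectation(const Forest &f, int j) {
  if (f.feature[j] < 0) return f.value[j];
  int a = f.yes[j], b = f.no[j];
  return (f.cover[a] * tree_expectation(f, a) +
          f.cover[b] * tree_expectation(f, b)) / f.cover[j];
}

static double tree_eval(const Forest &f, const double *x, int j) {
  while (f.feature[j] >= 0) {
    j = ((float)x[f.feature[j]] < (float)f.threshold[j]) ? f.yes[j] : f.no[j];
  }
  return f.value[j];
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix X, IntegerVector feature,
                  NumericVector threshold, IntegerVector yes,
                  IntegerVector no, NumericVector value, NumericVector cover,
                  IntegerVector roots, double base_score) {
  int n = X.nrow(), p = X.ncol(), T = roots.size();
  Forest f = {feature, threshold, yes, no, value, cover};
  NumericMatrix phi(n, p);
  double expected = base_score;
  for (int t = 0; t < T; ++t) expected += tree_expectation(f, roots[t]);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k) row[k] = X(i, k);
    double *phi_i = new double[p]();
    for (int t = 0; t < T; ++t) {
      Path m;
      tree_shap_recurse(f, row.data(), phi_i, roots[t], m, 1.0, 1.0, -1);
    }
    for (int k = 0; k < p; ++k) phi(i, k) = phi_i[k];
    delete[] phi_i;
  }
  return List::create(_["phi"] = phi, _["base_value"] = expected);
}

// [[Rcpp::export(name = ".treepredict_cpp")]]
NumericVector treepredict_cpp(NumericMatrix X, IntegerVector feature,
                              NumericVector threshold, IntegerVector yes,
                              IntegerVector no, NumericVector value,
                              NumericVector cover, IntegerVector roots,
                              double base_score) {
  int n = X.nrow(), p = X.ncol(), T = roots.size();
  Forest f = {feature, threshold, yes, no, value, cover};
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k) row[k] = X(i, k);
    double s = base_score;
    for (int t = 0; t < T; ++t) s += tree_eval(f, row.data(), roots[t]);
    out[i] = s;
  }
  return out;
}
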