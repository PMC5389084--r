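#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// SCAD-penalised least squares by cyclic coordinate descent on the
// standardised design.  The objective minimised is
//   (1/2n) ||y - b0 - X beta||^2 + sum_j p_lambda(|beta_j|)
// (the penalised least-squares criterion scaled by 1/n; same minimiser).
// On columns standardised to unit (population) variance the univariate
// coordinate problem has the exact closed-form SCAD solution below, so each
// coordinate update can only decrease the objective.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static inline double scad_update(double z, double lam, double a) {
  const double az = std::fabs(z);
  if (az <= 2.0 * lam) return soft(z, lam);
  if (az <= a * lam) return soft(z, a * lam / (a - 1.0)) / (1.0 - 1.0 / (a - 1.0));
  return z;
}

static inline double scad_pen(double b, double lam, double a) {
  b = std::fabs(b);
  if (b <= lam) return lam * b;
  if (b <= a * lam) return -(b * b - 2.0 * a * lam * b + lam * lam) / (2.0 * (a - 1.0));
  return (a + 1.0) * lam * lam / 2.0;
}

// [[Rcpp::export]]
double cpp_scad_penalty(double beta_abs, double lambda, double alpha) {
  return scad_pen(beta_abs, lambda, alpha);
}

struct StdDesign {
  int n, k;
  std::vector<double> X;    // column-major standardised design
  std::vector<double> yc;   // centred response
  std::vector<double> xm, xs;
  std::vector<char> keep;   // zero-variance columns are excluded
  double ybar;
};

// rows are 0-based indices into the full X / y
static StdDesign standardize(const NumericMatrix &X, const NumericVector &y,
                             const std::vector<int> &rows) {
  StdDesign d;
  d.n = rows.size();
  d.k = X.ncol();
  d.X.resize((size_t)d.n * d.k);
  d.yc.resize(d.n);
  d.xm.resize(d.k);
  d.xs.resize(d.k);
  d.keep.resize(d.k);
  double ybar = 0.0;
  for (int i = 0; i < d.n; ++i) ybar += y[rows[i]];
  ybar /= d.n;
  d.ybar = ybar;
  for (int i = 0; i < d.n; ++i) d.yc[i] = y[rows[i]] - ybar;
  for (int j = 0; j < d.k; ++j) {
    double m = 0.0;
    const double *col = &X(0, j);
    for (int i = 0; i < d.n; ++i) m += col[rows[i]];
    m /= d.n;
    double v = 0.0;
    for (int i = 0; i < d.n; ++i) {
      const double c = col[rows[i]] - m;
      v += c * c;
    }
    v /= d.n;
    const double s = std::sqrt(v);
    d.xm[j] = m;
    d.xs[j] = s;
    d.keep[j] = (s > 1e-12);
    double *out = &d.X[(size_t)j * d.n];
    if (d.keep[j]) {
      for (int i = 0; i < d.n; ++i) out[i] = (col[rows[i]] - m) / s;
    } else {
      std::fill(out, out + d.n, 0.0);
    }
  }
  return d;
}

static double lambda_max_of(const StdDesign &d) {
  double lm = 0.0;
  for (int j = 0; j < d.k; ++j) {
    if (!d.keep[j]) continue;
    const double *xj = &d.X[(size_t)j * d.n];
    double z = 0.0;
    for (int i = 0; i < d.n; ++i) z += xj[i] * d.yc[i];
    z = std::fabs(z) / d.n;
    if (z > lm) lm = z;
  }
  return lm;
}

// One coordinate-descent pass over the given index set; returns max abs
// coefficient change.  r is the current residual (length n).
static double cd_sweep(const StdDesign &d, const std::vector<int> &idx,
                       std::vector<double> &b, std::vector<double> &r,
                       double lam, double alpha) {
  double maxd = 0.0;
  const int n = d.n;
  for (size_t q = 0; q < idx.size(); ++q) {
    const int j = idx[q];
    if (!d.keep[j]) continue;
    const double *xj = &d.X[(size_t)j * n];
    double z = 0.0;
    for (int i = 0; i < n; ++i) z += xj[i] * r[i];
    z = z / n + b[j];
    const double bn = scad_update(z, lam, alpha);
    const double delta = b[j] - bn;
    if (delta != 0.0) {
      for (int i = 0; i < n; ++i) r[i] += xj[i] * delta;
      const double ad = std::fabs(delta);
      if (ad > maxd) maxd = ad;
      b[j] = bn;
    }
  }
  return maxd;
}

static double objective(const StdDesign &d, const std::vector<double> &b,
                        const std::vector<double> &r, double lam, double alpha) {
  double rss = 0.0;
  for (int i = 0; i < d.n; ++i) rss += r[i] * r[i];
  double pen = 0.0;
  for (int j = 0; j < d.k; ++j) pen += scad_pen(b[j], lam, alpha);
  return 0.5 * rss / d.n + pen;
}

// Gradient-screening cache shared across lambda steps of one path walk:
// z holds |x_j' r| / n for every inactive coordinate as of the residual
// snapshot rc; for coordinates active at caching time it holds +Inf.  Since
// ||x_j|| = sqrt(n) on the standardised design, the score of any coordinate
// can drift from its cached value by at most ||r - rc|| / sqrt(n), so
// coordinates with cached score + drift below lambda are provably
// non-violating and need no gradient evaluation.
struct ScreenState {
  std::vector<double> z, rc;
  bool valid;
  ScreenState() : valid(false) {}
};

// Solve along a decreasing lambda path with warm starts and active-set
// cycling.  b (standardised scale) and r are updated in place from the
// warm-start state the caller provides.
// Returns the number of lambda values actually solved: the path stops once a
// converged solution carries more than dfmax nonzero coefficients (the
// saturation guard for k >> n); solutions from that point on are not usable.
static int path_solve(const StdDesign &d, const std::vector<double> &lambda,
                      double alpha, double tol, int maxit, int dfmax,
                      std::vector<double> &b, std::vector<double> &r,
                      std::vector< std::vector<double> > *b_out,
                      std::vector<int> *niter_out, bool *converged,
                      ScreenState *ss = NULL) {
  const int k = d.k;
  const int n = d.n;
  *converged = true;
  std::vector<int> act;
  act.reserve(256);
  for (size_t l = 0; l < lambda.size(); ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool done = false;
    while (!done && it < maxit) {
      // converge on the current active set
      act.clear();
      for (int j = 0; j < k; ++j) if (b[j] != 0.0) act.push_back(j);
      if (!act.empty()) {
        while (it < maxit) {
          const double md = cd_sweep(d, act, b, r, lam, alpha);
          ++it;
          if (md < tol) break;
        }
      }
      // check-only KKT scan over the inactive coordinates: a zero coefficient
      // wants to move iff |x_j' r| / n exceeds lambda.  With a valid
      // screening cache only coordinates whose cached score plus the
      // residual-drift bound reaches lambda are evaluated; the cache is
      // refreshed by a full scan when the candidate set grows too large.
      bool violated = false;
      bool full_scan = true;
      if (ss && ss->valid) {
        double dr2 = 0.0;
        for (int i = 0; i < n; ++i) {
          const double e = r[i] - ss->rc[i];
          dr2 += e * e;
        }
        const double eps = std::sqrt(dr2 / n);
        int ncand = 0;
        for (int j = 0; j < k; ++j)
          if (b[j] == 0.0 && d.keep[j] && ss->z[j] + eps > lam) ++ncand;
        if (ncand <= k / 8) {
          full_scan = false;
          for (int j = 0; j < k; ++j) {
            if (b[j] != 0.0 || !d.keep[j] || ss->z[j] + eps <= lam) continue;
            const double *xj = &d.X[(size_t)j * n];
            double z = 0.0;
            for (int i = 0; i < n; ++i) z += xj[i] * r[i];
            z /= n;
            if (std::fabs(z) > lam) {
              const double bn = scad_update(z, lam, alpha);
              const double delta = -bn;
              for (int i = 0; i < n; ++i) r[i] += xj[i] * delta;
              b[j] = bn;
              violated = true;
            }
          }
        }
      }
      if (full_scan) {
        if (ss) {
          ss->z.assign(k, 0.0);
          ss->rc.assign(r.begin(), r.end());
        }
        for (int j = 0; j < k; ++j) {
          if (!d.keep[j]) continue;
          if (b[j] != 0.0) {
            if (ss) ss->z[j] = R_PosInf;
            continue;
          }
          const double *xj = &d.X[(size_t)j * n];
          double z = 0.0;
          for (int i = 0; i < n; ++i) z += xj[i] * r[i];
          z /= n;
          if (ss) ss->z[j] = std::fabs(z);
          if (std::fabs(z) > lam) {
            const double bn = scad_update(z, lam, alpha);
            const double delta = -bn;
            for (int i = 0; i < n; ++i) r[i] += xj[i] * delta;
            b[j] = bn;
            if (ss) ss->z[j] = R_PosInf;
            violated = true;
          }
        }
        if (ss) ss->valid = true;
      }
      ++it;
      if (!violated) done = true;
    }
    if (!done && it >= maxit) *converged = false;
    int nnz = 0;
    for (int j = 0; j < k; ++j) if (b[j] != 0.0) ++nnz;
    if (nnz > dfmax) return (int)l;
    if (b_out) (*b_out)[l] = b;
    if (niter_out) (*niter_out)[l] = it;
  }
  return (int)lambda.size();
}

static std::vector<int> as_rows(SEXP rowsSexp, int nfull) {
  std::vector<int> rows;
  if (Rf_isNull(rowsSexp)) {
    rows.resize(nfull);
    for (int i = 0; i < nfull; ++i) rows[i] = i;
  } else {
    IntegerVector rv(rowsSexp);
    rows.resize(rv.size());
    for (int i = 0; i < rv.size(); ++i) {
      rows[i] = rv[i] - 1;  // 1-based from R
      if (rows[i] < 0 || rows[i] >= nfull) stop("row index out of range");
    }
  }
  return rows;
}

static NumericVector make_lambda(const StdDesign &d, int nlambda,
                                 double lambda_min_ratio) {
  double lmax = lambda_max_of(d);
  if (lmax <= 0.0) lmax = 1e-3;  // degenerate (constant y): any grid gives 0
  NumericVector lam(nlambda);
  const double llmax = std::log(lmax), llmin = std::log(lmax * lambda_min_ratio);
  for (int l = 0; l < nlambda; ++l)
    lam[l] = std::exp(llmax + (llmin - llmax) * l / (nlambda - 1.0));
  return lam;
}

// Fit at a single lambda, recording the objective after every full
// coordinate-descent sweep (used to assert monotonicity).
// [[Rcpp::export]]
List cpp_scad_fit(NumericMatrix X, NumericVector y, double lambda,
                  double alpha, double tol, int maxit, SEXP rows) {
  std::vector<int> rr = as_rows(rows, X.nrow());
  StdDesign d = standardize(X, y, rr);
  const int k = d.k;
  std::vector<double> b(k, 0.0), r(d.yc);
  std::vector<int> all(k);
  for (int j = 0; j < k; ++j) all[j] = j;
  std::vector<double> obj;
  obj.push_back(objective(d, b, r, lambda, alpha));
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    const double maxd = cd_sweep(d, all, b, r, lambda, alpha);
    obj.push_back(objective(d, b, r, lambda, alpha));
    if (maxd < tol) { converged = true; break; }
  }
  NumericVector beta(k);
  double b0 = d.ybar;
  for (int j = 0; j < k; ++j) {
    beta[j] = d.keep[j] ? b[j] / d.xs[j] : 0.0;
    b0 -= beta[j] * d.xm[j];
  }
  return List::create(_["beta"] = beta, _["intercept"] = b0,
                      _["objective"] = NumericVector(obj.begin(), obj.end()),
                      _["converged"] = converged);
}

// Warm-started path fit; returns coefficients on the original scale.
// [[Rcpp::export]]
List cpp_scad_path(NumericMatrix X, NumericVector y, SEXP lambdaSexp,
                   int nlambda, double lambda_min_ratio, double alpha,
                   double tol, int maxit, SEXP rows, int dfmax) {
  std::vector<int> rr = as_rows(rows, X.nrow());
  StdDesign d = standardize(X, y, rr);
  NumericVector lam = Rf_isNull(lambdaSexp)
      ? make_lambda(d, nlambda, lambda_min_ratio)
      : NumericVector(lambdaSexp);
  std::vector<double> lamv(lam.begin(), lam.end());
  const int k = d.k, L = lamv.size();
  std::vector<double> b(k, 0.0), r(d.yc);
  std::vector< std::vector<double> > bout(L);
  std::vector<int> nit(L);
  bool converged;
  if (dfmax <= 0) dfmax = k;
  const int solved = path_solve(d, lamv, alpha, tol, maxit, dfmax, b, r,
                                &bout, &nit, &converged);
  for (int l = solved; l < L; ++l) { bout[l] = bout[solved > 0 ? solved - 1 : 0]; nit[l] = 0; }
  NumericMatrix beta(k, L);
  NumericVector b0(L);
  for (int l = 0; l < L; ++l) {
    double icpt = d.ybar;
    for (int j = 0; j < k; ++j) {
      const double bj = d.keep[j] ? bout[l][j] / d.xs[j] : 0.0;
      beta(j, l) = bj;
      icpt -= bj * d.xm[j];
    }
    b0[l] = icpt;
  }
  return List::create(_["beta"] = beta, _["intercept"] = b0,
                      _["lambda"] = lam,
                      _["niter"] = IntegerVector(nit.begin(), nit.end()),
                      _["n_solved"] = solved,
                      _["converged"] = converged);
}

// K-fold cross-validation over an auto-generated (or supplied) lambda grid,
// followed by a refit on all supplied rows at the CV-minimising lambda.
// foldid is per training row (1..nfolds, aligned with rows).  All folds are
// advanced together one lambda at a time so the walk down the grid can stop
// early once the CV curve has clearly passed its minimum (`patience` grid
// points without improvement); the expensive deep-overfit tail of the path
// is never solved.
// [[Rcpp::export]]
List cpp_scad_cv(NumericMatrix X, NumericVector y, IntegerVector rowsIdx,
                 IntegerVector foldid, SEXP lambdaSexp, int nlambda,
                 double lambda_min_ratio, double alpha, double tol, int maxit,
                 int dfmax, int patience = 8, SEXP testRows = R_NilValue) {
  const int nt = rowsIdx.size();
  if (foldid.size() != nt) stop("foldid must align with rows");
  std::vector<int> rr = as_rows(rowsIdx, X.nrow());
  StdDesign dfull = standardize(X, y, rr);
  NumericVector lam = Rf_isNull(lambdaSexp)
      ? make_lambda(dfull, nlambda, lambda_min_ratio)
      : NumericVector(lambdaSexp);
  std::vector<double> lamv(lam.begin(), lam.end());
  const int L = lamv.size(), k = X.ncol();
  int nfolds = 0;
  for (int i = 0; i < nt; ++i) nfolds = std::max(nfolds, foldid[i]);

  struct FoldState {
    StdDesign d;
    std::vector<double> b, r;
    std::vector<int> te;
    ScreenState ss;
    bool truncated;
  };
  std::vector<FoldState> fs;
  for (int f = 1; f <= nfolds; ++f) {
    FoldState st;
    std::vector<int> tr;
    for (int i = 0; i < nt; ++i) {
      if (foldid[i] == f) st.te.push_back(rr[i]); else tr.push_back(rr[i]);
    }
    if (st.te.empty() || (int)tr.size() < 2) continue;
    st.d = standardize(X, y, tr);
    st.b.assign(k, 0.0);
    st.r = st.d.yc;
    st.truncated = false;
    fs.push_back(st);
  }

  const int fdf_default = dfmax;
  NumericVector cvm(L, R_PosInf);
  int best = -1;
  double bestv = R_PosInf;
  bool conv_all = true;
  int evaluated = 0;
  for (int l = 0; l < L; ++l) {
    std::vector<double> lam1(1, lamv[l]);
    double sse = 0.0;
    int cnt = 0;
    for (size_t q = 0; q < fs.size(); ++q) {
      FoldState &st = fs[q];
      if (st.truncated) continue;
      bool conv;
      const int fdf = fdf_default > 0 ? fdf_default : st.d.n;
      // fold fits feed only the CV error curve; a tight sweep cap per lambda
      // avoids burning the budget on oscillating deep-overfit solutions
      const int maxit_cv = std::min(maxit, 20);
      const int solved = path_solve(st.d, lam1, alpha, tol, maxit_cv, fdf,
                                    st.b, st.r, NULL, NULL, &conv, &st.ss);
      if (!conv) conv_all = false;
      if (solved < 1) { st.truncated = true; continue; }
      std::vector<int> nz;
      for (int j = 0; j < k; ++j)
        if (st.d.keep[j] && st.b[j] != 0.0) nz.push_back(j);
      for (size_t t = 0; t < st.te.size(); ++t) {
        const int i = st.te[t];
        double pred = st.d.ybar;
        for (size_t q = 0; q < nz.size(); ++q) {
          const int j = nz[q];
          pred += st.b[j] / st.d.xs[j] * (X(i, j) - st.d.xm[j]);
        }
        const double e = y[i] - pred;
        sse += e * e;
        ++cnt;
      }
    }
    evaluated = l + 1;
    if (cnt > 0) {
      cvm[l] = sse / cnt;
      if (cvm[l] < bestv) { bestv = cvm[l]; best = l; }
    }
    bool all_trunc = true;
    for (size_t q = 0; q < fs.size(); ++q) if (!fs[q].truncated) all_trunc = false;
    if (all_trunc) break;
    if (best >= 0 && l - best >= patience) break;
  }
  if (best < 0) best = 0;  // every fold degenerate: fall back to lambda_max

  // refit on all rows at lambda[best]; no saturation guard here (the CV
  // minimiser sits well before saturation)
  std::vector<double> b(k, 0.0), r(dfull.yc);
  std::vector<double> lampath(lamv.begin(), lamv.begin() + best + 1);
  std::vector< std::vector<double> > bout(lampath.size());
  bool conv;
  ScreenState rss;
  path_solve(dfull, lampath, alpha, tol, maxit, k, b, r, &bout, NULL, &conv,
             &rss);
  if (!conv) conv_all = false;
  NumericVector beta(k);
  double b0 = dfull.ybar;
  for (int j = 0; j < k; ++j) {
    beta[j] = dfull.keep[j] ? b[j] / dfull.xs[j] : 0.0;
    b0 -= beta[j] * dfull.xm[j];
  }
  // out-of-sample predictions from the refit, using only the nonzero
  // coefficients (avoids materialising X subsets on the caller's side)
  NumericVector testPred;
  if (!Rf_isNull(testRows)) {
    IntegerVector te(testRows);
    testPred = NumericVector(te.size());
    std::vector<int> nzj;
    for (int j = 0; j < k; ++j) if (beta[j] != 0.0) nzj.push_back(j);
    for (int t = 0; t < te.size(); ++t) {
      const int i = te[t] - 1;
      double pred = b0;
      for (size_t q = 0; q < nzj.size(); ++q)
        pred += beta[nzj[q]] * X(i, nzj[q]);
      testPred[t] = pred;
    }
  }
  return List::create(_["lambda"] = lam, _["cvm"] = cvm,
                      _["lambda_selected"] = lamv[best],
                      _["index_selected"] = best + 1,
                      _["n_evaluated"] = evaluated,
                      _["beta"] = beta, _["intercept"] = b0,
                      _["test_pred"] = testPred,
                      _["converged"] = conv_all);
}
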