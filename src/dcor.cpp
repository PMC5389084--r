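#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pairwise-distance V-statistic estimator of the squared distance covariance
// for univariate x, y:
//   S1 = (1/n^2) sum_ij a_ij b_ij
//   S2 = [(1/n^2) sum_ij a_ij] [(1/n^2) sum_ij b_ij]
//   S3 = (1/n^3) sum_k rowsum_a[k] rowsum_b[k]
//   dcov2 = S1 + S2 - 2 S3
// with a_ij = |y_i - y_j|, b_ij = |x_i - x_j|.  Diagonal terms are zero, so
// only the i<j triangle is accumulated (doubled).

// [[Rcpp::export]]
double cpp_dcov2(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 observations");
  std::vector<double> rowa(n, 0.0), rowb(n, 0.0);
  double sab = 0.0, sa = 0.0, sb = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double b = std::fabs(xi - x[j]);
      const double a = std::fabs(yi - y[j]);
      sab += a * b; sa += a; sb += b;
      rowa[i] += a; rowa[j] += a;
      rowb[i] += b; rowb[j] += b;
    }
  }
  const double n2 = (double)n * n;
  double s3 = 0.0;
  for (int k = 0; k < n; ++k) s3 += rowa[k] * rowb[k];
  double v = 2.0 * sab / n2 + (2.0 * sa / n2) * (2.0 * sb / n2) - 2.0 * s3 / (n2 * n);
  return v > 0.0 ? v : 0.0;
}

// Squared distance correlation (the Dcorr of Eq-2 form, squared) of every
// column of X against y.  The y-distance matrix, its row sums and moments are
// computed once and shared across columns; per-column work is organised in
// short vectorisable passes over a row buffer.  Zero-variance columns get a
// score of exactly 0.
// [[Rcpp::export]]
NumericVector cpp_dcor2_scores(NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("phenotype length must equal nrow(X)");
  if (n < 2) stop("need at least 2 observations");

  // y-distance matrix (full, for contiguous row access) and its summaries
  std::vector<double> A((size_t)n * n);
  std::vector<double> rowa(n, 0.0);
  double sa = 0.0, saa = 0.0;
  for (int i = 0; i < n; ++i) {
    double ri = 0.0;
    const double yi = y[i];
    double *Ai = &A[(size_t)i * n];
    for (int j = 0; j < n; ++j) {
      const double a = std::fabs(yi - y[j]);
      Ai[j] = a;
      ri += a;
    }
    rowa[i] = ri;
    sa += ri;
  }
  for (int i = 0; i < n; ++i) {
    const double *Ai = &A[(size_t)i * n];
    for (int j = 0; j < n; ++j) saa += Ai[j] * Ai[j];
  }
  const double n2 = (double)n * n, n3 = n2 * (double)n;
  double s3yy = 0.0;
  for (int k = 0; k < n; ++k) s3yy += rowa[k] * rowa[k];
  const double dvyy = saa / n2 + (sa / n2) * (sa / n2) - 2.0 * s3yy / n3;

  NumericVector out(p);
  std::vector<double> rowb(n), buf(n);
  for (int jcol = 0; jcol < p; ++jcol) {
    const double *xc = &X(0, jcol);
    std::fill(rowb.begin(), rowb.end(), 0.0);
    double sab = 0.0, sb = 0.0, sbb = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = xc[i];
      const double *Ai = &A[(size_t)i * n];
      const int m = n - i - 1;
      double *bf = &buf[0];
      const double *xr = xc + i + 1;
      for (int t = 0; t < m; ++t) bf[t] = std::fabs(xi - xr[t]);
      double acc_ab = 0.0, acc_b = 0.0, acc_bb = 0.0, acc_ri = 0.0;
      const double *Ar = Ai + i + 1;
      for (int t = 0; t < m; ++t) acc_ab += Ar[t] * bf[t];
      for (int t = 0; t < m; ++t) { acc_b += bf[t]; acc_bb += bf[t] * bf[t]; }
      double *rb = &rowb[i + 1];
      for (int t = 0; t < m; ++t) { rb[t] += bf[t]; }
      acc_ri = acc_b;
      sab += acc_ab; sb += acc_b; sbb += acc_bb;
      rowb[i] += acc_ri;
    }
    double s3xy = 0.0, s3xx = 0.0;
    for (int k = 0; k < n; ++k) { s3xy += rowa[k] * rowb[k]; s3xx += rowb[k] * rowb[k]; }
    double dvxy = 2.0 * sab / n2 + (sa / n2) * (2.0 * sb / n2) - 2.0 * s3xy / n3;
    double dvxx = 2.0 * sbb / n2 + (2.0 * sb / n2) * (2.0 * sb / n2) - 2.0 * s3xx / n3;
    if (dvxy < 0.0) dvxy = 0.0;
    if (dvxx <= 0.0 || dvyy <= 0.0) { out[jcol] = 0.0; continue; }
    double r2 = dvxy / std::sqrt(dvxx * dvyy);
    if (r2 < 0.0) r2 = 0.0;
    if (r2 > 1.0) r2 = 1.0;
    out[jcol] = r2;
  }
  return out;
}
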