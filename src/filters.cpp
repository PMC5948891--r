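#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filtering of x into y with state z.
// b, a are same length nf, a[0] == 1. z has length nf - 1.
static void df2t(const double* b, const double* a, int nf,
                 const double* x, double* y, int n, double* z) {
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = z[0] + b[0] * xi;
    for (int j = 0; j < nf - 2; ++j)
      z[j] = z[j + 1] + b[j + 1] * xi - a[j + 1] * yi;
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
}

// [[Rcpp::export(name = ".filter_df2t")]]
NumericVector filter_df2t(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int nf = b.size(), n = x.size();
  if (a.size() != nf) stop("b and a must have equal length");
  if (zi.size() != nf - 1) stop("zi must have length length(b) - 1");
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  df2t(REAL(b), REAL(a), nf, REAL(x), REAL(y), n, z.data());
  return y;
}

// Zero-phase (forward-backward) filtering applied independently to every
// column of X, with even-reflection padding of length `padlen` and
// steady-state initial conditions `zi` scaled by the mean of the padded
// signal (a variant of the scipy/MATLAB filtfilt transient-suppression
// scheme: initializing with the mean rather than the first sample keeps
// near-DC filters -- e.g. a 0.05 Hz high-pass whose time constant far
// exceeds the window -- from injecting a slow offset transient, while a
// constant input still maps through its exact steady state).
// [[Rcpp::export(name = ".filtfilt_cols")]]
NumericMatrix filtfilt_cols(NumericVector b, NumericVector a, NumericMatrix X,
                            NumericVector zi, int padlen) {
  const int nf = b.size(), n = X.nrow(), nc = X.ncol();
  if (a.size() != nf) stop("b and a must have equal length");
  if (zi.size() != nf - 1) stop("zi must have length length(b) - 1");
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  const int next = n + 2 * padlen;
  NumericMatrix Y(n, nc);
  std::vector<double> ext(next), tmp(next), z(nf - 1);
  const double* pb = REAL(b);
  const double* pa = REAL(a);
  for (int c = 0; c < nc; ++c) {
    const double* x = &X(0, c);
    // even (mirror) reflection about the end points: keeps the extension at
    // the signal's own level, so near-DC filters see no artificial pedestal
    for (int i = 0; i < padlen; ++i) ext[i] = x[padlen - i];
    for (int i = 0; i < n; ++i) ext[padlen + i] = x[i];
    for (int i = 0; i < padlen; ++i) ext[padlen + n + i] = x[n - 2 - i];
    // forward pass
    double m = 0.0;
    for (int i = 0; i < next; ++i) m += ext[i];
    m /= next;
    for (int j = 0; j < nf - 1; ++j) z[j] = zi[j] * m;
    df2t(pb, pa, nf, ext.data(), tmp.data(), next, z.data());
    // backward pass
    std::reverse(tmp.begin(), tmp.end());
    m = 0.0;
    for (int i = 0; i < next; ++i) m += tmp[i];
    m /= next;
    for (int j = 0; j < nf - 1; ++j) z[j] = zi[j] * m;
    df2t(pb, pa, nf, tmp.data(), ext.data(), next, z.data());
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; ++i) Y(i, c) = ext[padlen + i];
  }
  return Y;
}
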