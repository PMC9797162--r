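#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect (edge-duplicating) boundary index: ... c b a | a b c ...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// k x k median filter, reflect padding, k odd.
// [[Rcpp::export]]
NumericMatrix cpp_medfilt2(NumericMatrix x, int k) {
  const int n = x.nrow(), m = x.ncol(), r = k / 2, kk = k * k;
  NumericMatrix out(n, m);
  std::vector<double> buf(kk);
  const int mid = kk / 2;  // kk odd
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      int q = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect_idx(j + dj, m);
        const double* col = &x(0, jj);
        for (int di = -r; di <= r; ++di)
          buf[q++] = col[reflect_idx(i + di, n)];
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Separable correlation with reflect padding.
// kv runs along rows (vertical), kh along columns (horizontal);
// av/ah are the 0-based kernel origin indices:
// out(i,j) = sum_p sum_q kv[p] kh[q] x(i + p - av, j + q - ah).
// The vertical pass copies each column into a reflect-padded buffer and
// accumulates kernel taps as contiguous axpy sweeps, which keeps both
// passes vectorizable.
// [[Rcpp::export]]
NumericMatrix cpp_sepfilt2(NumericMatrix x, NumericVector kv, int av,
                           NumericVector kh, int ah) {
  const int n = x.nrow(), m = x.ncol(), lv = kv.size(), lh = kh.size();
  NumericMatrix tmp(n, m), out(n, m);
  std::vector<double> buf(n + lv);
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    for (int t = 0; t < n + lv - 1; ++t)
      buf[t] = col[reflect_idx(t - av, n)];
    double* tc = &tmp(0, j);
    for (int i = 0; i < n; ++i) tc[i] = 0.0;
    for (int p = 0; p < lv; ++p) {
      const double w = kv[p];
      const double* b = &buf[p];
      for (int i = 0; i < n; ++i) tc[i] += w * b[i];
    }
  }
  for (int j = 0; j < m; ++j) {
    double* oc = &out(0, j);
    for (int i = 0; i < n; ++i) oc[i] = 0.0;
    for (int q = 0; q < lh; ++q) {
      const double w = kh[q];
      const double* tc = &tmp(0, reflect_idx(j + q - ah, m));
      for (int i = 0; i < n; ++i) oc[i] += w * tc[i];
    }
  }
  return out;
}
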