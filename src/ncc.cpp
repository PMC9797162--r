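#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Normalized cross-correlation of templ against every valid placement in
// image ("valid" mode). out(i,j) corresponds to the template's top-left
// pixel at image(i,j). Windows with (near-)zero variance get NCC 0; a
// zero-variance template is an error.
// [[Rcpp::export]]
NumericMatrix cpp_ncc_map(NumericMatrix image, NumericMatrix templ) {
  const int H = image.nrow(), W = image.ncol();
  const int h = templ.nrow(), w = templ.ncol();
  if (h > H || w > W) stop("template larger than image");
  const int nH = H - h + 1, nW = W - w + 1;
  const double n = (double)h * (double)w;

  double tsum = 0.0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) tsum += templ(i, j);
  const double tmean = tsum / n;
  std::vector<double> T0((size_t)h * w);
  double tss = 0.0, t0sum = 0.0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double v = templ(i, j) - tmean;
      T0[(size_t)j * h + i] = v;
      tss += v * v;
      t0sum += v;
    }
  if (tss <= 1e-24) stop("zero-variance template");
  const double tden = std::sqrt(tss);

  // summed-area tables of image and image^2, (H+1) x (W+1)
  std::vector<double> S1((size_t)(H + 1) * (W + 1), 0.0);
  std::vector<double> S2((size_t)(H + 1) * (W + 1), 0.0);
  for (int j = 1; j <= W; ++j) {
    double c1 = 0.0, c2 = 0.0;
    const double* col = &image(0, j - 1);
    for (int i = 1; i <= H; ++i) {
      double v = col[i - 1];
      c1 += v;
      c2 += v * v;
      S1[(size_t)j * (H + 1) + i] = S1[(size_t)(j - 1) * (H + 1) + i] + c1;
      S2[(size_t)j * (H + 1) + i] = S2[(size_t)(j - 1) * (H + 1) + i] + c2;
    }
  }
  const size_t HH = H + 1;
  NumericMatrix out(nH, nW);
  const double* img = &image(0, 0);
  for (int j0 = 0; j0 < nW; ++j0) {
    for (int i0 = 0; i0 < nH; ++i0) {
      double dot = 0.0;
      for (int tj = 0; tj < w; ++tj) {
        const double* ic = img + (size_t)(j0 + tj) * H + i0;
        const double* tc = &T0[(size_t)tj * h];
        // independent accumulators keep the reduction pipelined
        double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
        int ti = 0;
        for (; ti + 4 <= h; ti += 4) {
          a0 += ic[ti] * tc[ti];
          a1 += ic[ti + 1] * tc[ti + 1];
          a2 += ic[ti + 2] * tc[ti + 2];
          a3 += ic[ti + 3] * tc[ti + 3];
        }
        for (; ti < h; ++ti) a0 += ic[ti] * tc[ti];
        dot += (a0 + a1) + (a2 + a3);
      }
      const double s1 = S1[(size_t)(j0 + w) * HH + i0 + h]
                      - S1[(size_t)j0 * HH + i0 + h]
                      - S1[(size_t)(j0 + w) * HH + i0]
                      + S1[(size_t)j0 * HH + i0];
      const double s2 = S2[(size_t)(j0 + w) * HH + i0 + h]
                      - S2[(size_t)j0 * HH + i0 + h]
                      - S2[(size_t)(j0 + w) * HH + i0]
                      + S2[(size_t)j0 * HH + i0];
      const double var = s2 - s1 * s1 / n;
      if (var <= 1e-20 * (s2 + 1e-300)) {
        out(i0, j0) = 0.0;
        continue;
      }
      // dot is sum I*T0; subtract window-mean * sum(T0) (~0, rounding guard)
      const double num = dot - (s1 / n) * t0sum;
      out(i0, j0) = num / (std::sqrt(var) * tden);
    }
  }
  return out;
}
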