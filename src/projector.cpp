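#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Chord interval [t0,t1] of ray p0 + t*d through one primitive.
// type 0 = ellipsoid (par = semi-axes a,b,c), type 1 = finite cylinder
// (par = unit axis wx,wy,wz, radius, half-length). Returns false on miss.
static bool prim_interval(int type, const double* cen, const double* par,
                          const double* p0, const double* d,
                          double& t0, double& t1) {
  if (type == 0) {
    double A = 0.0, B = 0.0, C = -1.0;
    for (int k = 0; k < 3; ++k) {
      double q = (p0[k] - cen[k]) / par[k];
      double dd = d[k] / par[k];
      A += dd * dd;
      B += 2.0 * q * dd;
      C += q * q;
    }
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0.0 || A <= 0.0) return false;
    double s = std::sqrt(disc);
    t0 = (-B - s) / (2.0 * A);
    t1 = (-B + s) / (2.0 * A);
    return true;
  }
  // cylinder: split ray into components parallel/perpendicular to axis w
  const double* w = par;
  double r = par[3], h = par[4];
  double m[3];
  for (int k = 0; k < 3; ++k) m[k] = p0[k] - cen[k];
  double mw = m[0] * w[0] + m[1] * w[1] + m[2] * w[2];
  double dw = d[0] * w[0] + d[1] * w[1] + d[2] * w[2];
  double mp[3], dp[3];
  for (int k = 0; k < 3; ++k) {
    mp[k] = m[k] - mw * w[k];
    dp[k] = d[k] - dw * w[k];
  }
  double A = dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2];
  double ta, tb;  // interval from the infinite cylinder shell
  if (A < 1e-14) {  // ray parallel to the axis
    double rr = mp[0] * mp[0] + mp[1] * mp[1] + mp[2] * mp[2];
    if (rr > r * r) return false;
    ta = -INFINITY; tb = INFINITY;
  } else {
    double B = 2.0 * (mp[0] * dp[0] + mp[1] * dp[1] + mp[2] * dp[2]);
    double C = mp[0] * mp[0] + mp[1] * mp[1] + mp[2] * mp[2] - r * r;
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0.0) return false;
    double s = std::sqrt(disc);
    ta = (-B - s) / (2.0 * A);
    tb = (-B + s) / (2.0 * A);
  }
  // slab |mw + t*dw| <= h along the axis
  double sa, sb;
  if (std::fabs(dw) < 1e-14) {
    if (std::fabs(mw) > h) return false;
    sa = -INFINITY; sb = INFINITY;
  } else {
    sa = (-h - mw) / dw;
    sb = (h - mw) / dw;
    if (sa > sb) std::swap(sa, sb);
  }
  t0 = std::max(ta, sa);
  t1 = std::min(tb, sb);
  return t1 > t0;
}

// [[Rcpp::export]]
double cpp_path_length(int type, NumericVector cen, NumericVector par,
                       NumericVector p0, NumericVector d) {
  double t0, t1;
  if (!prim_interval(type, cen.begin(), par.begin(), p0.begin(), d.begin(),
                     t0, t1))
    return 0.0;
  return t1 - t0;
}

// Parallel-beam line integrals of mu over a detector grid.
// Ray direction d = (cos theta, sin theta, 0); detector axes
// u_dir = (-sin theta, cos theta, 0), v_dir = (0, 0, 1).
// Overlapping primitives are resolved per elementary ray segment by
// precedence (largest prec wins). Output: rows = v, cols = u.
// [[Rcpp::export]]
NumericMatrix cpp_line_integrals(NumericVector u_mm, NumericVector v_mm,
                                 double theta_rad, IntegerVector type,
                                 NumericMatrix center, NumericMatrix param,
                                 NumericVector mu, IntegerVector prec) {
  const int nu = u_mm.size(), nv = v_mm.size(), np = type.size();
  NumericMatrix out(nv, nu);
  const double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  const double d[3] = {ct, st, 0.0};
  std::vector<double> cen(3 * np), par(5 * np);
  for (int p = 0; p < np; ++p) {
    for (int k = 0; k < 3; ++k) cen[3 * p + k] = center(p, k);
    for (int k = 0; k < 5; ++k) par[5 * p + k] = param(p, k);
  }
  std::vector<double> h0(np), h1(np), hmu(np);
  std::vector<int> hprec(np);
  std::vector<double> bp(2 * np);
  for (int j = 0; j < nu; ++j) {
    const double u = u_mm[j];
    for (int i = 0; i < nv; ++i) {
      const double v = v_mm[i];
      const double p0[3] = {-u * st, u * ct, v};
      int nh = 0;
      for (int p = 0; p < np; ++p) {
        double t0, t1;
        if (prim_interval(type[p], &cen[3 * p], &par[5 * p], p0, d, t0, t1)) {
          h0[nh] = t0; h1[nh] = t1; hmu[nh] = mu[p]; hprec[nh] = prec[p];
          ++nh;
        }
      }
      if (nh == 0) continue;
      double acc = 0.0;
      if (nh == 1) {
        acc = hmu[0] * (h1[0] - h0[0]);
      } else {
        int nb = 0;
        for (int p = 0; p < nh; ++p) { bp[nb++] = h0[p]; bp[nb++] = h1[p]; }
        std::sort(bp.begin(), bp.begin() + nb);
        for (int s = 0; s + 1 < nb; ++s) {
          double a = bp[s], b = bp[s + 1];
          if (b <= a) continue;
          double tm = 0.5 * (a + b);
          int best = -1;
          double bmu = 0.0;
          for (int p = 0; p < nh; ++p) {
            if (h0[p] <= tm && tm < h1[p] && hprec[p] > best) {
              best = hprec[p];
              bmu = hmu[p];
            }
          }
          if (best >= 0) acc += bmu * (b - a);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
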