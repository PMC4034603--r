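#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hann-windowed sinc, 7-voxel support per axis (radius 3, window half-width 3.5)
static const int SINC_R = 3;

static inline double hann_sinc(double d) {
  const double radius = SINC_R + 0.5;
  double ad = std::fabs(d);
  if (ad >= radius) return 0.0;
  if (ad < 1e-12) return 1.0;
  double s = std::sin(M_PI * d) / (M_PI * d);
  return s * 0.5 * (1.0 + std::cos(M_PI * d / radius));
}

// Sample a zero-padded 3-D array at continuous 0-based voxel coordinates.
// a: padded array (dims d + 2p per axis), d: original dims, p: pad width.
// method: 0 nearest, 1 trilinear, 2 windowed sinc.
// Points outside the field of view return 0.
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector a, IntegerVector d, int p,
                                NumericVector si, NumericVector sj,
                                NumericVector sk, int method) {
  const int n = si.size();
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int p1 = d1 + 2 * p, p2 = d2 + 2 * p;
  const double *A = a.begin();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = si[q], y = sj[q], z = sk[q];
    if (x <= -0.5 || x >= d1 - 0.5 || y <= -0.5 || y >= d2 - 0.5 ||
        z <= -0.5 || z >= d3 - 0.5) { out[q] = 0.0; continue; }
    if (method == 0) {
      int i = (int)std::lround(x), j = (int)std::lround(y),
          k = (int)std::lround(z);
      out[q] = A[(i + p) + (long)p1 * ((j + p) + (long)p2 * (k + p))];
    } else if (method == 1) {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
          k0 = (int)std::floor(z);
      double fx = x - i0, fy = y - j0, fz = z - k0;
      double v = 0.0;
      for (int di = 0; di <= 1; ++di)
        for (int dj = 0; dj <= 1; ++dj)
          for (int dk = 0; dk <= 1; ++dk) {
            double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                       (dk ? fz : 1 - fz);
            v += w * A[(i0 + di + p) +
                       (long)p1 * ((j0 + dj + p) + (long)p2 * (k0 + dk + p))];
          }
      out[q] = v;
    } else {
      int ic = (int)std::lround(x), jc = (int)std::lround(y),
          kc = (int)std::lround(z);
      double wx[2 * SINC_R + 1], wy[2 * SINC_R + 1], wz[2 * SINC_R + 1];
      double sx = 0, sy = 0, sz = 0;
      for (int m = -SINC_R; m <= SINC_R; ++m) {
        wx[m + SINC_R] = hann_sinc(x - (ic + m)); sx += wx[m + SINC_R];
        wy[m + SINC_R] = hann_sinc(y - (jc + m)); sy += wy[m + SINC_R];
        wz[m + SINC_R] = hann_sinc(z - (kc + m)); sz += wz[m + SINC_R];
      }
      // per-axis normalisation reproduces constants exactly
      double v = 0.0;
      for (int mi = 0; mi <= 2 * SINC_R; ++mi) {
        double wxi = wx[mi] / sx;
        int ii = ic + mi - SINC_R + p;
        for (int mj = 0; mj <= 2 * SINC_R; ++mj) {
          double wxy = wxi * wy[mj] / sy;
          long base = ii + (long)p1 * ((jc + mj - SINC_R + p) +
                                       (long)p2 * (kc - SINC_R + p));
          for (int mk = 0; mk <= 2 * SINC_R; ++mk) {
            v += wxy * (wz[mk] / sz) * A[base];
            base += (long)p1 * p2;
          }
        }
      }
      out[q] = v;
    }
  }
  return out;
}
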