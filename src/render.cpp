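// Synthetic scene renderer: pinhole projection with radial distortion,
// ray/heightfield intersection by fixed-point depth iteration, procedural
// multiplicative speckle texture shared across bands so that local image
// features are detectable and consistent between colour and NIR renders.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double hash01(uint32_t ix, uint32_t iy, uint32_t seed) {
  uint32_t h = ix * 374761393u + iy * 668265263u + seed * 2246822519u;
  h = (h ^ (h >> 13)) * 1274126177u;
  h ^= (h >> 16);
  return (double)h / 4294967295.0;
}

static inline double latval(int ix, int iy, uint32_t seed) {
  return 2.0 * hash01((uint32_t)(ix + 100000), (uint32_t)(iy + 100000), seed) - 1.0;
}

// smooth value noise at (x, y) lattice units
static double value_noise(double x, double y, uint32_t seed) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  fx = fx * fx * (3 - 2 * fx);
  fy = fy * fy * (3 - 2 * fy);
  double v00 = latval(x0, y0, seed), v10 = latval(x0 + 1, y0, seed);
  double v01 = latval(x0, y0 + 1, seed), v11 = latval(x0 + 1, y0 + 1, seed);
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// multiplicative speckle texture field, fixed seed, world coordinates
static double speckle(double x, double y, NumericVector scales,
                      NumericVector weights, double amp, uint32_t seed) {
  double t = 0;
  for (int k = 0; k < scales.size(); ++k)
    t += weights[k] * value_noise(x / scales[k] + 31.7 * (k + 1),
                                  y / scales[k] - 17.3 * (k + 1), seed + 7u * k);
  double out = 1.0 + amp * t;
  if (out < 0.2) out = 0.2;
  if (out > 1.8) out = 1.8;
  return out;
}

static inline double bilin(const NumericMatrix& g, double cell, double x, double y) {
  int ny = g.nrow(), nx = g.ncol();
  double xi = x / cell, yi = y / cell;
  if (xi < 0) xi = 0; if (xi > nx - 1) xi = nx - 1;
  if (yi < 0) yi = 0; if (yi > ny - 1) yi = ny - 1;
  int x0 = (int)std::floor(xi); if (x0 > nx - 2) x0 = nx - 2;
  int y0 = (int)std::floor(yi); if (y0 > ny - 2) y0 = ny - 2;
  double fx = xi - x0, fy = yi - y0;
  return g(y0, x0) * (1 - fx) * (1 - fy) + g(y0 + 1, x0) * (1 - fx) * fy +
         g(y0, x0 + 1) * fx * (1 - fy) + g(y0 + 1, x0 + 1) * fx * fy;
}

// Box-Muller gaussian from counter-based hash (fully deterministic)
static inline double hash_normal(uint32_t i, uint32_t seed) {
  double u1 = hash01(i, 0x9e3779b9u, seed);
  double u2 = hash01(i, 0x85ebca6bu, seed);
  if (u1 < 1e-12) u1 = 1e-12;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// [[Rcpp::export]]
NumericVector render_view_cpp(NumericMatrix height, double cell,
                              IntegerMatrix cover, NumericMatrix base_vals,
                              NumericMatrix R, NumericVector C,
                              double f, double cx, double cy,
                              double k1, double k2, int width, int height_px,
                              NumericVector tex_scales, NumericVector tex_weights,
                              double tex_amp, int tex_seed,
                              double noise_sd, int noise_seed) {
  int nb = base_vals.ncol();
  NumericVector out(height_px * width * nb);
  out.attr("dim") = IntegerVector::create(height_px, width, nb);
  int ny = cover.nrow(), nx = cover.ncol();

  double ground = bilin(height, cell, C[0], C[1]);
  if (C[2] <= ground)
    stop("camera pose is below the terrain surface");

  for (int v = 0; v < height_px; ++v) {
    for (int u = 0; u < width; ++u) {
      // undistort pixel -> normalised camera coords
      double xd = (u - cx) / f, yd = (v - cy) / f;
      double xn = xd, yn = yd;
      for (int it = 0; it < 6; ++it) {
        double r2 = xn * xn + yn * yn;
        double d = 1 + k1 * r2 + k2 * r2 * r2;
        xn = xd / d; yn = yd / d;
      }
      // world ray: d_w = R^T (xn, yn, 1)
      double dx = R(0, 0) * xn + R(1, 0) * yn + R(2, 0);
      double dy = R(0, 1) * xn + R(1, 1) * yn + R(2, 1);
      double dz = R(0, 2) * xn + R(1, 2) * yn + R(2, 2);
      if (dz >= -1e-9) continue;  // ray not descending: leave 0
      double zest = ground;
      double x = C[0], y = C[1];
      for (int it = 0; it < 14; ++it) {
        double t = (zest - C[2]) / dz;
        x = C[0] + t * dx; y = C[1] + t * dy;
        zest = bilin(height, cell, x, y);
      }
      int ix = (int)std::lround(x / cell); if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
      int iy = (int)std::lround(y / cell); if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
      int cls = cover(iy, ix) - 1;
      double tex = speckle(x, y, tex_scales, tex_weights, tex_amp, (uint32_t)tex_seed);
      for (int b = 0; b < nb; ++b) {
        double val = base_vals(cls, b) * tex;
        if (noise_sd > 0) {
          uint32_t idx = (uint32_t)((v * width + u) * nb + b);
          val += noise_sd * hash_normal(idx, (uint32_t)noise_seed);
        }
        out[v + height_px * (u + width * b)] = val > 0 ? val : 0;
      }
    }
  }
  return out;
}
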