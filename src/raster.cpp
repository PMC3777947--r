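// Raster products: plan-view rasterisation of a 2.5D triangulated terrain
// (barycentric elevation, per-face slope/aspect, covering-face id),
// z-buffer depth rendering for texture-visibility tests, and orthomosaic
// blending (per-cell weighted average of up to four assigned views).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List rasterize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                        NumericVector face_a, NumericVector face_b,
                        double x0, double y0, double cell, int nx, int ny,
                        double nodata = -9999.0) {
  NumericMatrix elev(ny, nx), va(ny, nx), vb(ny, nx);
  IntegerMatrix fid(ny, nx);
  std::fill(elev.begin(), elev.end(), nodata);
  std::fill(va.begin(), va.end(), nodata);
  std::fill(vb.begin(), vb.end(), nodata);
  std::fill(fid.begin(), fid.end(), -1);
  int m = F.nrow();
  for (int f = 0; f < m; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
    double bx = V(i1, 0), by = V(i1, 1), bz = V(i1, 2);
    double cx = V(i2, 0), cy = V(i2, 1), cz = V(i2, 2);
    double den = (by - ay) * (cx - ax) - (bx - ax) * (cy - ay);
    if (std::fabs(den) < 1e-14) continue;
    int cx0 = std::max(0, (int)std::floor((std::min({ax, bx, cx}) - x0) / cell));
    int cx1 = std::min(nx - 1, (int)std::ceil((std::max({ax, bx, cx}) - x0) / cell));
    int cy0 = std::max(0, (int)std::floor((std::min({ay, by, cy}) - y0) / cell));
    int cy1 = std::min(ny - 1, (int)std::ceil((std::max({ay, by, cy}) - y0) / cell));
    for (int iy = cy0; iy <= cy1; ++iy) {
      double py = y0 + iy * cell;
      for (int ix = cx0; ix <= cx1; ++ix) {
        double pxx = x0 + ix * cell;
        double l1 = ((by - cy) * (pxx - cx) + (cx - bx) * (py - cy)) /
                    ((by - cy) * (ax - cx) + (cx - bx) * (ay - cy));
        double l2 = ((cy - ay) * (pxx - cx) + (ax - cx) * (py - cy)) /
                    ((by - cy) * (ax - cx) + (cx - bx) * (ay - cy));
        double l3 = 1 - l1 - l2;
        if (l1 < -1e-9 || l2 < -1e-9 || l3 < -1e-9) continue;
        elev(iy, ix) = l1 * az + l2 * bz + l3 * cz;
        va(iy, ix) = face_a[f];
        vb(iy, ix) = face_b[f];
        fid(iy, ix) = f + 1;
      }
    }
  }
  return List::create(_["elevation"] = elev, _["a"] = va, _["b"] = vb,
                      _["face"] = fid);
}

struct Cam2 {
  double R[9], C[3], f, cx, cy, k1, k2;
};

static Cam2 cam_from(NumericMatrix R, NumericVector C, NumericVector intr) {
  Cam2 c;
  for (int i = 0; i < 9; ++i) c.R[i] = R[i];
  for (int i = 0; i < 3; ++i) c.C[i] = C[i];
  c.f = intr[0]; c.cx = intr[1]; c.cy = intr[2]; c.k1 = intr[3]; c.k2 = intr[4];
  return c;
}

static inline bool proj2(const Cam2& c, double X, double Y, double Z,
                         double& u, double& v, double& z) {
  double d0 = X - c.C[0], d1 = Y - c.C[1], d2 = Z - c.C[2];
  double x0 = c.R[0] * d0 + c.R[3] * d1 + c.R[6] * d2;
  double x1 = c.R[1] * d0 + c.R[4] * d1 + c.R[7] * d2;
  double x2 = c.R[2] * d0 + c.R[5] * d1 + c.R[8] * d2;
  z = x2;
  if (x2 <= 1e-9) return false;
  double x = x0 / x2, y = x1 / x2;
  double r2 = x * x + y * y;
  double dd = 1 + c.k1 * r2 + c.k2 * r2 * r2;
  u = c.f * x * dd + c.cx;
  v = c.f * y * dd + c.cy;
  return true;
}

// z-buffer depth render of the mesh into one camera (image-space
// rasterisation at a given downscale factor)
// [[Rcpp::export]]
NumericMatrix depth_render_cpp(NumericMatrix V, IntegerMatrix F,
                               NumericMatrix R, NumericVector C,
                               NumericVector intr, int width, int height,
                               int downscale = 2) {
  Cam2 cam = cam_from(R, C, intr);
  int w = width / downscale, h = height / downscale;
  NumericMatrix depth(h, w);
  std::fill(depth.begin(), depth.end(), R_PosInf);
  int n = V.nrow();
  std::vector<double> pu(n), pv(n), pz(n);
  std::vector<char> okv(n);
  for (int i = 0; i < n; ++i) {
    double u, v, z;
    okv[i] = proj2(cam, V(i, 0), V(i, 1), V(i, 2), u, v, z);
    pu[i] = u / downscale; pv[i] = v / downscale; pz[i] = z;
  }
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    if (!okv[a] || !okv[b] || !okv[c]) continue;
    double xmin = std::min({pu[a], pu[b], pu[c]}), xmax = std::max({pu[a], pu[b], pu[c]});
    double ymin = std::min({pv[a], pv[b], pv[c]}), ymax = std::max({pv[a], pv[b], pv[c]});
    if (xmax < 0 || ymax < 0 || xmin > w - 1 || ymin > h - 1) continue;
    int ix0 = std::max(0, (int)std::floor(xmin)), ix1 = std::min(w - 1, (int)std::ceil(xmax));
    int iy0 = std::max(0, (int)std::floor(ymin)), iy1 = std::min(h - 1, (int)std::ceil(ymax));
    double den = (pv[b] - pv[a]) * (pu[c] - pu[a]) - (pu[b] - pu[a]) * (pv[c] - pv[a]);
    if (std::fabs(den) < 1e-12) continue;
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix) {
        double l1 = ((pv[b] - pv[c]) * (ix - pu[c]) + (pu[c] - pu[b]) * (iy - pv[c])) /
                    ((pv[b] - pv[c]) * (pu[a] - pu[c]) + (pu[c] - pu[b]) * (pv[a] - pv[c]));
        double l2 = ((pv[c] - pv[a]) * (ix - pu[c]) + (pu[a] - pu[c]) * (iy - pv[c])) /
                    ((pv[b] - pv[c]) * (pu[a] - pu[c]) + (pu[c] - pu[b]) * (pv[a] - pv[c]));
        double l3 = 1 - l1 - l2;
        if (l1 < -1e-6 || l2 < -1e-6 || l3 < -1e-6) continue;
        double z = l1 * pz[a] + l2 * pz[b] + l3 * pz[c];
        if (z < depth(iy, ix)) depth(iy, ix) = z;
      }
  }
  return depth;
}

static inline double bilin_band(const NumericVector& img, int h, int w,
                                int band, double x, double y) {
  if (x < 0) x = 0; if (x > w - 1) x = w - 1;
  if (y < 0) y = 0; if (y > h - 1) y = h - 1;
  int x0 = (int)x; if (x0 > w - 2) x0 = w - 2;
  int y0 = (int)y; if (y0 > h - 2) y0 = h - 2;
  double fx = x - x0, fy = y - y0;
  const double* p = &img[0] + (size_t)h * w * band;
  return p[y0 + h * x0] * (1 - fx) * (1 - fy) + p[y0 + 1 + h * x0] * (1 - fx) * fy +
         p[y0 + h * (x0 + 1)] * fx * (1 - fy) + p[y0 + 1 + h * (x0 + 1)] * fx * fy;
}

// Orthomosaic blending for one band set.
// faceid/elev: plan rasters; assign: nface x 4 image ids (1-based, 0 = none);
// weights: nface x 4; images: list of h x w x nb arrays; cams: list of
// (R, C, intr) per image (parallel lists).
// [[Rcpp::export]]
List blend_mosaic_cpp(IntegerMatrix faceid, NumericMatrix elev,
                      double x0, double y0, double cell,
                      IntegerMatrix assign, NumericMatrix weights,
                      List images, List Rs, List Cs, List intrs,
                      int nbands, double nodata = -9999.0) {
  int ny = faceid.nrow(), nx = faceid.ncol();
  int nimg = images.size();
  std::vector<Cam2> cams(nimg);
  std::vector<NumericVector> imgs(nimg);
  std::vector<int> ih(nimg), iw(nimg);
  for (int i = 0; i < nimg; ++i) {
    cams[i] = cam_from(Rs[i], Cs[i], intrs[i]);
    imgs[i] = images[i];
    IntegerVector d = imgs[i].attr("dim");
    ih[i] = d[0]; iw[i] = d[1];
  }
  NumericVector out(ny * nx * nbands);
  out.attr("dim") = IntegerVector::create(ny, nx, nbands);
  std::fill(out.begin(), out.end(), nodata);
  IntegerMatrix count(ny, nx);
  for (int iy = 0; iy < ny; ++iy) {
    double Y = y0 + iy * cell;
    for (int ix = 0; ix < nx; ++ix) {
      int f = faceid(iy, ix);
      if (f <= 0) continue;
      double X = x0 + ix * cell, Z = elev(iy, ix);
      double wsum = 0;
      std::vector<double> acc(nbands, 0.0);
      int used = 0;
      for (int k = 0; k < 4; ++k) {
        int im = assign(f - 1, k);
        if (im <= 0) continue;
        double u, v, z;
        if (!proj2(cams[im - 1], X, Y, Z, u, v, z)) continue;
        if (u < 1 || u > iw[im - 1] - 2 || v < 1 || v > ih[im - 1] - 2) continue;
        double w = weights(f - 1, k);
        for (int b = 0; b < nbands; ++b)
          acc[b] += w * bilin_band(imgs[im - 1], ih[im - 1], iw[im - 1], b, u, v);
        wsum += w;
        ++used;
      }
      if (used == 0 || wsum <= 0) continue;
      for (int b = 0; b < nbands; ++b)
        out[iy + (size_t)ny * (ix + (size_t)nx * b)] = acc[b] / wsum;
      count(iy, ix) = used;
    }
  }
  return List::create(_["values"] = out, _["count"] = count);
}
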