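// Two-view densification: for each reference image on a regular pixel
// grid, search the epipolar line in a partner view by zero-mean
// normalised cross-correlation (ZNCC) of fixed patches, refine the depth
// to subpixel by parabolic interpolation of the correlation peak, and
// triangulate.  A deliberately simplified two-view scheme standing in for
// full patch-expansion multi-view stereo; it reaches the target density
// of roughly one 3D point per cell_px x cell_px patch on textured scenes.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Cam {
  double R[9], C[3], f, cx, cy, k1, k2;
  int w, h;
};

// R is column-major; (R v)_i = sum_j R[j*3+i] v_j.  Verified against the
// R-side projection in tests.
static inline bool project(const Cam& c, const double* X, double& u, double& v,
                           double& z) {
  double Xc[3];
  double d0 = X[0] - c.C[0], d1 = X[1] - c.C[1], d2 = X[2] - c.C[2];
  Xc[0] = c.R[0] * d0 + c.R[3] * d1 + c.R[6] * d2;
  Xc[1] = c.R[1] * d0 + c.R[4] * d1 + c.R[7] * d2;
  Xc[2] = c.R[2] * d0 + c.R[5] * d1 + c.R[8] * d2;
  z = Xc[2];
  if (z <= 1e-9) return false;
  double x = Xc[0] / z, y = Xc[1] / z;
  double r2 = x * x + y * y;
  double dd = 1 + c.k1 * r2 + c.k2 * r2 * r2;
  u = c.f * x * dd + c.cx;
  v = c.f * y * dd + c.cy;
  return true;
}

static inline double sample_bilinear(const NumericMatrix& img, double x, double y) {
  int w = img.ncol(), h = img.nrow();
  if (x < 0) x = 0; if (x > w - 1) x = w - 1;
  if (y < 0) y = 0; if (y > h - 1) y = h - 1;
  int x0 = (int)x; if (x0 > w - 2) x0 = w - 2;
  int y0 = (int)y; if (y0 > h - 2) y0 = h - 2;
  double fx = x - x0, fy = y - y0;
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0 + 1, x0) * (1 - fx) * fy +
         img(y0, x0 + 1) * fx * (1 - fy) + img(y0 + 1, x0 + 1) * fx * fy;
}

static Cam make_cam(NumericMatrix R, NumericVector C, NumericVector intr,
                    int w, int h) {
  Cam c;
  for (int i = 0; i < 9; ++i) c.R[i] = R[i];
  for (int i = 0; i < 3; ++i) c.C[i] = C[i];
  c.f = intr[0]; c.cx = intr[1]; c.cy = intr[2]; c.k1 = intr[3]; c.k2 = intr[4];
  c.w = w; c.h = h;
  return c;
}

// [[Rcpp::export]]
List densify_pair_cpp(NumericMatrix ref, NumericMatrix par,
                      NumericMatrix R_ref, NumericVector C_ref, NumericVector i_ref,
                      NumericMatrix R_par, NumericVector C_par, NumericVector i_par,
                      int cell_px, int half, double zncc_min,
                      double dmin, double dmax, double step_px = 0.75,
                      double min_var = 1e-10) {
  Cam cr = make_cam(R_ref, C_ref, i_ref, ref.ncol(), ref.nrow());
  Cam cp = make_cam(R_par, C_par, i_par, par.ncol(), par.nrow());
  int border = half + cell_px;
  int np = (2 * half + 1) * (2 * half + 1);
  std::vector<double> pr(np), pp(np);
  std::vector<double> Xs, Ys, Zs, Zn; std::vector<int> Us, Vs;

  for (int v = border; v < cr.h - border; v += cell_px) {
    for (int u = border; u < cr.w - border; u += cell_px) {
      // reference patch
      double mr = 0;
      int k = 0;
      for (int dy = -half; dy <= half; ++dy)
        for (int dx = -half; dx <= half; ++dx) {
          pr[k] = ref(v + dy, u + dx);
          mr += pr[k]; ++k;
        }
      mr /= np;
      double vr = 0;
      for (int i = 0; i < np; ++i) { pr[i] -= mr; vr += pr[i] * pr[i]; }
      if (vr < min_var) continue;
      vr = std::sqrt(vr);
      // undistort + world ray
      double xd = (u - cr.cx) / cr.f, yd = (v - cr.cy) / cr.f;
      double xn = xd, yn = yd;
      for (int it = 0; it < 6; ++it) {
        double r2 = xn * xn + yn * yn;
        double dd = 1 + cr.k1 * r2 + cr.k2 * r2 * r2;
        xn = xd / dd; yn = yd / dd;
      }
      double dw[3];
      dw[0] = cr.R[0] * xn + cr.R[1] * yn + cr.R[2];
      dw[1] = cr.R[3] * xn + cr.R[4] * yn + cr.R[5];
      dw[2] = cr.R[6] * xn + cr.R[7] * yn + cr.R[8];
      // epipolar segment length in partner image
      double u0, v0, u1, v1, zz;
      double X0[3] = {cr.C[0] + dmin * dw[0], cr.C[1] + dmin * dw[1], cr.C[2] + dmin * dw[2]};
      double X1[3] = {cr.C[0] + dmax * dw[0], cr.C[1] + dmax * dw[1], cr.C[2] + dmax * dw[2]};
      if (!project(cp, X0, u0, v0, zz) || !project(cp, X1, u1, v1, zz)) continue;
      double seg = std::sqrt((u1 - u0) * (u1 - u0) + (v1 - v0) * (v1 - v0));
      int nsteps = (int)std::ceil(seg / step_px);
      if (nsteps < 6) nsteps = 6;
      if (nsteps > 400) nsteps = 400;
      int besti = -1;
      double bestz = -2, prevz = -2;
      std::vector<double> scores(nsteps + 1, -2);
      for (int s = 0; s <= nsteps; ++s) {
        double t = dmin + (dmax - dmin) * s / nsteps;
        double X[3] = {cr.C[0] + t * dw[0], cr.C[1] + t * dw[1], cr.C[2] + t * dw[2]};
        double pu, pv, pz;
        if (!project(cp, X, pu, pv, pz)) continue;
        if (pu < half + 1 || pu > cp.w - half - 2 || pv < half + 1 || pv > cp.h - half - 2)
          continue;
        double mp = 0;
        k = 0;
        for (int dy = -half; dy <= half; ++dy)
          for (int dx = -half; dx <= half; ++dx) {
            pp[k] = sample_bilinear(par, pu + dx, pv + dy);
            mp += pp[k]; ++k;
          }
        mp /= np;
        double vp = 0, cc = 0;
        for (int i = 0; i < np; ++i) {
          double d = pp[i] - mp;
          vp += d * d; cc += d * pr[i];
        }
        if (vp < min_var) continue;
        double z = cc / (vr * std::sqrt(vp));
        scores[s] = z;
        if (z > bestz) { bestz = z; besti = s; }
      }
      if (besti < 1 || besti >= nsteps || bestz < zncc_min) continue;
      // peak uniqueness: a second, separated near-maximum means the
      // texture is ambiguous along this epipolar segment
      int near_best = 0;
      for (int s = 0; s <= nsteps; ++s)
        if (scores[s] > bestz - 0.03 && std::abs(s - besti) > 4) ++near_best;
      if (near_best > 0) continue;
      double zl = scores[besti - 1], zc = scores[besti], zrr = scores[besti + 1];
      double denom = zl - 2 * zc + zrr;
      double off = (std::fabs(denom) > 1e-12) ? 0.5 * (zl - zrr) / denom : 0;
      if (off < -1) off = -1; if (off > 1) off = 1;
      double t = dmin + (dmax - dmin) * (besti + off) / nsteps;
      Xs.push_back(cr.C[0] + t * dw[0]);
      Ys.push_back(cr.C[1] + t * dw[1]);
      Zs.push_back(cr.C[2] + t * dw[2]);
      Zn.push_back(bestz);
      Us.push_back(u); Vs.push_back(v);
    }
  }
  int n = Xs.size();
  NumericMatrix X(n, 3);
  NumericVector zncc(n); IntegerVector uu(n), vv(n);
  for (int i = 0; i < n; ++i) {
    X(i, 0) = Xs[i]; X(i, 1) = Ys[i]; X(i, 2) = Zs[i];
    zncc[i] = Zn[i]; uu[i] = Us[i]; vv[i] = Vs[i];
  }
  return List::create(_["X"] = X, _["zncc"] = zncc, _["u"] = uu, _["v"] = vv);
}
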