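// Local invariant feature detection: multi-scale-lite Harris corners with
// subpixel refinement and upright SIFT-style gradient-histogram
// descriptors (4x4 cells x 8 orientation bins, L2-normalised, clipped).
// Near-nadir aerial surveys at a fixed altitude need translation
// repeatability and contrast invariance far more than full scale/rotation
// invariance, so the detector runs at a single smoothing scale and the
// descriptor is not rotated.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static void gauss_blur(const std::vector<double>& in, std::vector<double>& out,
                       int w, int h, double sigma) {
  int r = (int)std::ceil(3 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto& v : k) v /= s;
  std::vector<double> tmp(w * h);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double a = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i; if (xx < 0) xx = 0; if (xx >= w) xx = w - 1;
        a += k[i + r] * in[y * w + xx];
      }
      tmp[y * w + x] = a;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double a = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i; if (yy < 0) yy = 0; if (yy >= h) yy = h - 1;
        a += k[i + r] * tmp[yy * w + x];
      }
      out[y * w + x] = a;
    }
}

struct Kp { double x, y, resp; };

// [[Rcpp::export]]
List detect_features_cpp(NumericMatrix img, double sigma = 1.2,
                         double harris_k = 0.06, double rel_thresh = 1e-4,
                         int nms_radius = 3, int max_features = 1500,
                         int border = 18) {
  int h = img.nrow(), w = img.ncol();
  std::vector<double> I(w * h), B(w * h);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) I[y * w + x] = img(y, x);
  gauss_blur(I, B, w, h, sigma);

  // gradients (central differences on the smoothed image)
  std::vector<double> gx(w * h, 0), gy(w * h, 0);
  for (int y = 1; y < h - 1; ++y)
    for (int x = 1; x < w - 1; ++x) {
      gx[y * w + x] = 0.5 * (B[y * w + x + 1] - B[y * w + x - 1]);
      gy[y * w + x] = 0.5 * (B[(y + 1) * w + x] - B[(y - 1) * w + x]);
    }
  std::vector<double> xx(w * h), yy(w * h), xy(w * h);
  for (int i = 0; i < w * h; ++i) { xx[i] = gx[i] * gx[i]; yy[i] = gy[i] * gy[i]; xy[i] = gx[i] * gy[i]; }
  std::vector<double> sxx(w * h), syy(w * h), sxy(w * h);
  gauss_blur(xx, sxx, w, h, 2.0);
  gauss_blur(yy, syy, w, h, 2.0);
  gauss_blur(xy, sxy, w, h, 2.0);
  std::vector<double> Rsp(w * h, 0);
  double rmax = 0;
  for (int i = 0; i < w * h; ++i) {
    double det = sxx[i] * syy[i] - sxy[i] * sxy[i];
    double tr = sxx[i] + syy[i];
    Rsp[i] = det - harris_k * tr * tr;
    if (Rsp[i] > rmax) rmax = Rsp[i];
  }
  if (rmax <= 0) {
    return List::create(_["keypoints"] = NumericMatrix(0, 2),
                        _["descriptors"] = NumericMatrix(0, 128),
                        _["response"] = NumericVector(0));
  }
  double thr = rel_thresh * rmax;

  std::vector<Kp> kps;
  for (int y = border; y < h - border; ++y)
    for (int x = border; x < w - border; ++x) {
      double r0 = Rsp[y * w + x];
      if (r0 < thr) continue;
      bool mx = true;
      for (int dy = -nms_radius; dy <= nms_radius && mx; ++dy)
        for (int dx = -nms_radius; dx <= nms_radius; ++dx) {
          if (dx == 0 && dy == 0) continue;
          if (Rsp[(y + dy) * w + x + dx] > r0) { mx = false; break; }
        }
      if (!mx) continue;
      // subpixel quadratic refinement
      double dxv = 0.5 * (Rsp[y * w + x + 1] - Rsp[y * w + x - 1]);
      double dyv = 0.5 * (Rsp[(y + 1) * w + x] - Rsp[(y - 1) * w + x]);
      double dxx = Rsp[y * w + x + 1] - 2 * r0 + Rsp[y * w + x - 1];
      double dyy = Rsp[(y + 1) * w + x] - 2 * r0 + Rsp[(y - 1) * w + x];
      double ox = (dxx < -1e-12) ? -dxv / dxx : 0;
      double oy = (dyy < -1e-12) ? -dyv / dyy : 0;
      if (std::fabs(ox) > 0.6) ox = 0;
      if (std::fabs(oy) > 0.6) oy = 0;
      kps.push_back({x + ox, y + oy, r0});
    }
  std::sort(kps.begin(), kps.end(), [](const Kp& a, const Kp& b) {
    if (a.resp != b.resp) return a.resp > b.resp;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });
  if ((int)kps.size() > max_features) kps.resize(max_features);

  int n = kps.size();
  NumericMatrix K(n, 2);
  NumericMatrix D(n, 128);
  NumericVector resp(n);
  const int nbins = 8, ncell = 4, half = 8;  // 16x16 support
  for (int i = 0; i < n; ++i) {
    K(i, 0) = kps[i].x; K(i, 1) = kps[i].y; resp[i] = kps[i].resp;
    int cxp = (int)std::lround(kps[i].x), cyp = (int)std::lround(kps[i].y);
    double hist[128] = {0};
    for (int dy = -half; dy < half; ++dy)
      for (int dx = -half; dx < half; ++dx) {
        int px = cxp + dx, py = cyp + dy;
        if (px < 1 || px >= w - 1 || py < 1 || py >= h - 1) continue;
        double gxx = gx[py * w + px], gyy = gy[py * w + px];
        double mag = std::sqrt(gxx * gxx + gyy * gyy);
        double ang = std::atan2(gyy, gxx);  // [-pi, pi]
        double wgt = std::exp(-0.5 * (dx * dx + dy * dy) / (half * half));
        // soft-binned cell and orientation coordinates
        double cxc = (dx + half) / (2.0 * half) * ncell - 0.5;
        double cyc = (dy + half) / (2.0 * half) * ncell - 0.5;
        double ob = (ang + M_PI) / (2 * M_PI) * nbins - 0.5;
        int cx0 = (int)std::floor(cxc), cy0 = (int)std::floor(cyc);
        int ob0 = (int)std::floor(ob);
        double fx = cxc - cx0, fy = cyc - cy0, fo = ob - ob0;
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            for (int c = 0; c < 2; ++c) {
              int ci = cx0 + a, cj = cy0 + b, ok = (ob0 + c + nbins) % nbins;
              if (ci < 0 || ci >= ncell || cj < 0 || cj >= ncell) continue;
              double wt = wgt * mag * (a ? fx : 1 - fx) * (b ? fy : 1 - fy) * (c ? fo : 1 - fo);
              hist[(cj * ncell + ci) * nbins + ok] += wt;
            }
      }
    double nrm = 0;
    for (int j = 0; j < 128; ++j) nrm += hist[j] * hist[j];
    nrm = std::sqrt(nrm) + 1e-12;
    for (int j = 0; j < 128; ++j) { hist[j] /= nrm; if (hist[j] > 0.2) hist[j] = 0.2; }
    nrm = 0;
    for (int j = 0; j < 128; ++j) nrm += hist[j] * hist[j];
    nrm = std::sqrt(nrm) + 1e-12;
    for (int j = 0; j < 128; ++j) D(i, j) = hist[j] / nrm;
  }
  return List::create(_["keypoints"] = K, _["descriptors"] = D,
                      _["response"] = resp);
}
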