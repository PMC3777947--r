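// Structure-from-motion numerical core: batch midpoint triangulation,
// reprojection residuals, and a Levenberg-Marquardt bundle adjuster with
// analytic Jacobians, Huber-robustified reprojection error and a Schur
// complement on the point blocks.  Shared intrinsics (focal, k1, k2) per
// camera body are refined jointly (self-calibration); principal point is
// held at the image centre.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static arma::mat33 rodrigues_cpp(const arma::vec3& w) {
  double th = arma::norm(w);
  arma::mat33 I = arma::eye(3, 3);
  if (th < 1e-14) {
    arma::mat33 K = {{0, -w(2), w(1)}, {w(2), 0, -w(0)}, {-w(1), w(0), 0}};
    return I + K;
  }
  arma::vec3 k = w / th;
  arma::mat33 K = {{0, -k(2), k(1)}, {k(2), 0, -k(0)}, {-k(1), k(0), 0}};
  return I + std::sin(th) * K + (1 - std::cos(th)) * (K * K);
}

// Midpoint triangulation for each point from grouped observations.
// obs_pt gives the point index (0-based) of each observation; xn, yn are
// undistorted normalised coordinates; R (3x3xncam) world->cam, C (ncam x 3).
// [[Rcpp::export]]
List triangulate_points_cpp(IntegerVector obs_cam, IntegerVector obs_pt,
                            NumericVector xn, NumericVector yn,
                            arma::cube R, arma::mat C, int n_pts) {
  arma::mat X(n_pts, 3, arma::fill::zeros);
  arma::mat A(3, 3);
  arma::vec b(3);
  std::vector<arma::mat33> Aacc(n_pts, arma::mat33(arma::fill::zeros));
  std::vector<arma::vec3> bacc(n_pts, arma::vec3(arma::fill::zeros));
  std::vector<int> cnt(n_pts, 0);
  int n = obs_cam.size();
  for (int i = 0; i < n; ++i) {
    int c = obs_cam[i], p = obs_pt[i];
    arma::vec3 d = R.slice(c).t() * arma::vec3({xn[i], yn[i], 1.0});
    d /= arma::norm(d);
    arma::mat33 P = arma::eye(3, 3) - d * d.t();
    Aacc[p] += P;
    bacc[p] += P * C.row(c).t();
    cnt[p]++;
  }
  LogicalVector ok(n_pts);
  for (int p = 0; p < n_pts; ++p) {
    if (cnt[p] < 2) { ok[p] = false; continue; }
    arma::vec3 x;
    bool s = arma::solve(x, Aacc[p], bacc[p], arma::solve_opts::no_approx);
    ok[p] = s && x.is_finite();
    if (ok[p]) X.row(p) = x.t();
  }
  return List::create(_["X"] = X, _["ok"] = ok);
}

// Reprojection residual norms (pixels) and depths for observations.
// intr rows: f, cx, cy, k1, k2 per body; body: body index per camera.
// [[Rcpp::export]]
List reproject_cpp(IntegerVector obs_cam, IntegerVector obs_pt,
                   NumericVector u, NumericVector v,
                   arma::cube R, arma::mat C, IntegerVector body,
                   arma::mat intr, arma::mat pts) {
  int n = obs_cam.size();
  NumericVector err(n), depth(n);
  for (int i = 0; i < n; ++i) {
    int c = obs_cam[i], b = body[c];
    arma::vec3 Xc = R.slice(c) * (pts.row(obs_pt[i]).t() - C.row(c).t());
    depth[i] = Xc(2);
    if (Xc(2) <= 1e-9) { err[i] = 1e9; continue; }
    double x = Xc(0) / Xc(2), y = Xc(1) / Xc(2);
    double r2 = x * x + y * y;
    double d = 1 + intr(b, 3) * r2 + intr(b, 4) * r2 * r2;
    double du = intr(b, 0) * x * d + intr(b, 1) - u[i];
    double dv = intr(b, 0) * y * d + intr(b, 2) - v[i];
    err[i] = std::sqrt(du * du + dv * dv);
  }
  return List::create(_["err"] = err, _["depth"] = depth);
}

struct ObsJac {
  int cam, pt, body;
  arma::mat Jc;  // 2x6 (rot, centre) — empty if camera fixed
  arma::mat Ji;  // 2x3 (f, k1, k2) — empty if intrinsics fixed
  arma::mat Jp;  // 2x3
  arma::vec2 r;
};

// [[Rcpp::export]]
List bundle_adjust_cpp(arma::cube R, arma::mat C, IntegerVector body,
                       arma::mat intr, arma::mat pts,
                       IntegerVector obs_cam, IntegerVector obs_pt,
                       NumericVector u, NumericVector v,
                       IntegerVector fixed_cams, bool fit_intrinsics,
                       double huber_px = 2.0, int max_iter = 30,
                       double lambda_init = 1e-3, double tol = 1e-8,
                       Nullable<NumericVector> focal_prior = R_NilValue,
                       double focal_prior_sd = 0.0) {
  int ncam = R.n_slices, npts = pts.n_rows, nobs = obs_cam.size();
  int nbody = intr.n_rows;
  std::vector<int> camrank(ncam, -1);
  std::vector<bool> fixed(ncam, false);
  for (int i = 0; i < fixed_cams.size(); ++i) fixed[fixed_cams[i]] = true;
  int ncf = 0;
  for (int c = 0; c < ncam; ++c) if (!fixed[c]) camrank[c] = ncf++;
  int ni = fit_intrinsics ? 3 * nbody : 0;
  int Nc = 6 * ncf + ni;

  // group observations by point
  std::vector<std::vector<int>> ptobs(npts);
  for (int i = 0; i < nobs; ++i) ptobs[obs_pt[i]].push_back(i);

  // soft prior on focal length (nominal-focal regulariser): keeps the
  // focal/height ambiguity of near-planar nadir surveys from collapsing
  // while being far weaker than the image evidence when it exists
  NumericVector fp;
  bool use_prior = false;
  if (focal_prior.isNotNull() && focal_prior_sd > 0) {
    fp = focal_prior.get();
    use_prior = true;
  }

  auto cost_fn = [&](const cube& Rx, const mat& Cx, const mat& intx,
                     const mat& ptsx) {
    double cost = 0;
    if (use_prior)
      for (int b = 0; b < nbody; ++b) {
        double d = (intx(b, 0) - fp[b]) / focal_prior_sd;
        cost += 0.5 * d * d;
      }
    for (int i = 0; i < nobs; ++i) {
      int c = obs_cam[i], b = body[c];
      arma::vec3 Xc = Rx.slice(c) * (ptsx.row(obs_pt[i]).t() - Cx.row(c).t());
      if (Xc(2) <= 1e-9) { cost += 1e6; continue; }
      double x = Xc(0) / Xc(2), y = Xc(1) / Xc(2);
      double r2 = x * x + y * y;
      double d = 1 + intx(b, 3) * r2 + intx(b, 4) * r2 * r2;
      double du = intx(b, 0) * x * d + intx(b, 1) - u[i];
      double dv = intx(b, 0) * y * d + intx(b, 2) - v[i];
      double e = std::sqrt(du * du + dv * dv);
      cost += (e <= huber_px) ? 0.5 * e * e
                              : huber_px * (e - 0.5 * huber_px);
    }
    return cost;
  };

  double lambda = lambda_init;
  double cost = cost_fn(R, C, intr, pts);
  std::vector<double> trace;
  trace.push_back(cost);
  std::vector<ObsJac> J(nobs);

  for (int iter = 0; iter < max_iter; ++iter) {
    // --- linearise ---
    mat U(Nc, Nc, arma::fill::zeros);
    vec gc(Nc, arma::fill::zeros);
    std::vector<arma::mat33> V(npts, arma::mat33(arma::fill::zeros));
    std::vector<arma::vec3> gp(npts, arma::vec3(arma::fill::zeros));
    for (int i = 0; i < nobs; ++i) {
      int c = obs_cam[i], b = body[c], p = obs_pt[i];
      arma::vec3 Xc = R.slice(c) * (pts.row(p).t() - C.row(c).t());
      double z = std::max(Xc(2), 1e-9);
      double x = Xc(0) / z, y = Xc(1) / z;
      double r2 = x * x + y * y;
      double f = intr(b, 0), k1 = intr(b, 3), k2 = intr(b, 4);
      double d = 1 + k1 * r2 + k2 * r2 * r2;
      double dd = k1 + 2 * k2 * r2;  // dd/dr2
      double pu = f * x * d + intr(b, 1);
      double pv = f * y * d + intr(b, 2);
      arma::vec2 r = {pu - u[i], pv - v[i]};
      double e = arma::norm(r);
      double w = (e <= huber_px) ? 1.0 : std::sqrt(huber_px / e);
      // d(pixel)/d(normalised x,y)
      arma::mat22 A = {{f * (d + 2 * x * x * dd), f * (2 * x * y * dd)},
                       {f * (2 * x * y * dd), f * (d + 2 * y * y * dd)}};
      // d(normalised)/d(Xc)
      arma::mat B(2, 3);
      B(0, 0) = 1 / z; B(0, 1) = 0;     B(0, 2) = -x / z;
      B(1, 0) = 0;     B(1, 1) = 1 / z; B(1, 2) = -y / z;
      arma::mat AB = A * B;  // 2x3, d(pixel)/dXc
      ObsJac& oj = J[i];
      oj.cam = c; oj.pt = p; oj.body = b;
      oj.r = w * r;
      // point
      oj.Jp = w * AB * R.slice(c);
      if (!fixed[c]) {
        arma::mat33 S = {{0, -Xc(2), Xc(1)}, {Xc(2), 0, -Xc(0)}, {-Xc(1), Xc(0), 0}};
        arma::mat Jr = -AB * S;          // wrt left-composed rotation delta
        arma::mat Jt = -AB * R.slice(c); // wrt camera centre
        oj.Jc = arma::join_rows(Jr, Jt) * w;
      } else oj.Jc.reset();
      if (fit_intrinsics) {
        arma::mat Ji(2, 3);
        Ji(0, 0) = x * d; Ji(1, 0) = y * d;
        Ji(0, 1) = f * x * r2; Ji(1, 1) = f * y * r2;
        Ji(0, 2) = f * x * r2 * r2; Ji(1, 2) = f * y * r2 * r2;
        oj.Ji = w * Ji;
      } else oj.Ji.reset();
      // accumulate
      V[p] += oj.Jp.t() * oj.Jp;
      gp[p] += oj.Jp.t() * oj.r;
      int c0 = 6 * camrank[c];
      int i0 = 6 * ncf + 3 * b;
      if (!fixed[c]) {
        U.submat(c0, c0, c0 + 5, c0 + 5) += oj.Jc.t() * oj.Jc;
        gc.subvec(c0, c0 + 5) += oj.Jc.t() * oj.r;
      }
      if (fit_intrinsics) {
        U.submat(i0, i0, i0 + 2, i0 + 2) += oj.Ji.t() * oj.Ji;
        gc.subvec(i0, i0 + 2) += oj.Ji.t() * oj.r;
        if (!fixed[c]) {
          arma::mat cross = oj.Jc.t() * oj.Ji;
          U.submat(c0, i0, c0 + 5, i0 + 2) += cross;
          U.submat(i0, c0, i0 + 2, c0 + 5) += cross.t();
        }
      }
    }

    if (use_prior && fit_intrinsics) {
      for (int b = 0; b < nbody; ++b) {
        int i0 = 6 * ncf + 3 * b;
        double w = 1.0 / (focal_prior_sd * focal_prior_sd);
        U(i0, i0) += w;
        gc(i0) += w * (intr(b, 0) - fp[b]);
      }
    }

    bool accepted = false;
    for (int attempt = 0; attempt < 8 && !accepted; ++attempt) {
      // damped blocks
      mat Ud = U;
      for (int k = 0; k < Nc; ++k) Ud(k, k) += lambda * (U(k, k) + 1e-12);
      std::vector<arma::mat33> Vinv(npts);
      for (int p = 0; p < npts; ++p) {
        arma::mat33 Vd = V[p];
        for (int k = 0; k < 3; ++k) Vd(k, k) += lambda * (V[p](k, k) + 1e-12);
        if (ptobs[p].empty()) { Vinv[p] = arma::mat33(arma::fill::zeros); continue; }
        Vinv[p] = arma::inv(Vd);
      }
      // Schur complement
      mat S = Ud;
      vec rhs = -gc;
      for (int p = 0; p < npts; ++p) {
        if (ptobs[p].empty()) continue;
        // gather W blocks for this point
        std::vector<std::pair<int, arma::mat>> Ws;  // (col offset, rows x 3)
        for (int oi : ptobs[p]) {
          ObsJac& oj = J[oi];
          if (!fixed[oj.cam]) {
            arma::mat Wc = oj.Jc.t() * oj.Jp;  // 6x3
            Ws.push_back({6 * camrank[oj.cam], Wc});
          }
          if (fit_intrinsics) {
            arma::mat Wi = oj.Ji.t() * oj.Jp;  // 3x3
            Ws.push_back({6 * ncf + 3 * oj.body, Wi});
          }
        }
        arma::vec3 vg = Vinv[p] * gp[p];
        for (size_t a = 0; a < Ws.size(); ++a) {
          int ra = Ws[a].first, na = Ws[a].second.n_rows;
          rhs.subvec(ra, ra + na - 1) += Ws[a].second * vg;
          arma::mat WV = Ws[a].second * Vinv[p];
          for (size_t bb = 0; bb < Ws.size(); ++bb) {
            int rb = Ws[bb].first, nb2 = Ws[bb].second.n_rows;
            S.submat(ra, rb, ra + na - 1, rb + nb2 - 1) -=
              WV * Ws[bb].second.t();
          }
        }
      }
      vec dc;
      bool solved = arma::solve(dc, S, rhs, arma::solve_opts::likely_sympd +
                                arma::solve_opts::no_approx);
      if (!solved || !dc.is_finite()) { lambda *= 5; continue; }
      // back-substitute points
      cube Rn = R; mat Cn = C; mat intrn = intr; mat ptsn = pts;
      for (int c = 0; c < ncam; ++c) {
        if (fixed[c]) continue;
        int c0 = 6 * camrank[c];
        arma::vec3 dr = dc.subvec(c0, c0 + 2);
        arma::vec3 dt = dc.subvec(c0 + 3, c0 + 5);
        Rn.slice(c) = rodrigues_cpp(dr) * R.slice(c);
        Cn.row(c) = C.row(c) + dt.t();
      }
      if (fit_intrinsics) {
        for (int b = 0; b < nbody; ++b) {
          int i0 = 6 * ncf + 3 * b;
          intrn(b, 0) += dc(i0);
          intrn(b, 3) += dc(i0 + 1);
          intrn(b, 4) += dc(i0 + 2);
        }
      }
      for (int p = 0; p < npts; ++p) {
        if (ptobs[p].empty()) continue;
        arma::vec3 acc = gp[p];
        for (int oi : ptobs[p]) {
          ObsJac& oj = J[oi];
          if (!fixed[oj.cam]) {
            int c0 = 6 * camrank[oj.cam];
            acc += (oj.Jc.t() * oj.Jp).t() * dc.subvec(c0, c0 + 5);
          }
          if (fit_intrinsics) {
            int i0 = 6 * ncf + 3 * oj.body;
            acc += (oj.Ji.t() * oj.Jp).t() * dc.subvec(i0, i0 + 2);
          }
        }
        arma::vec3 dp = -Vinv[p] * acc;
        ptsn.row(p) = pts.row(p) + dp.t();
      }
      double newcost = cost_fn(Rn, Cn, intrn, ptsn);
      if (newcost < cost) {
        R = Rn; C = Cn; intr = intrn; pts = ptsn;
        double rel = (cost - newcost) / std::max(cost, 1e-12);
        cost = newcost;
        trace.push_back(cost);
        lambda = std::max(lambda / 3, 1e-12);
        accepted = true;
        if (rel < tol) iter = max_iter;  // converged
      } else {
        lambda *= 5;
      }
    }
    if (!accepted) break;
  }

  // final unweighted reprojection RMSE
  double se = 0;
  for (int i = 0; i < nobs; ++i) {
    int c = obs_cam[i], b = body[c];
    arma::vec3 Xc = R.slice(c) * (pts.row(obs_pt[i]).t() - C.row(c).t());
    double z = std::max(Xc(2), 1e-9);
    double x = Xc(0) / z, y = Xc(1) / z;
    double r2 = x * x + y * y;
    double d = 1 + intr(b, 3) * r2 + intr(b, 4) * r2 * r2;
    double du = intr(b, 0) * x * d + intr(b, 1) - u[i];
    double dv = intr(b, 0) * y * d + intr(b, 2) - v[i];
    se += du * du + dv * dv;
  }
  return List::create(_["R"] = R, _["C"] = C, _["intr"] = intr,
                      _["pts"] = pts,
                      _["cost_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["rmse"] = std::sqrt(se / std::max(nobs, 1)));
}
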