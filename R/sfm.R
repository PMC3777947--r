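#' @name sfm
#' @title Incremental structure-from-motion
#' @description
#' The reconstruction engine: starting from an initial image pair with good
#' parallax, camera poses are added one at a time by robust
#' perspective-n-point, scene points are triangulated from their tracks,
#' and the whole model (poses, points and the shared intrinsics of each
#' camera body) is periodically refined by bundle adjustment.  Colour and
#' near-infrared images are placed in one common model; cross-band tracks
#' provide the glue.  The result is a complete, scale-less reconstruction
#' with arbitrary global orientation and position.
NULL

# flatten tracks into an observation table (track, img, x, y)
track_obs <- function(tracks) {
  if (length(tracks) == 0)
    return(data.frame(track = integer(0), img = integer(0),
                      x = numeric(0), y = numeric(0)))
  n <- vapply(tracks, nrow, 0L)
  data.frame(track = rep(seq_along(tracks), n),
             img = unlist(lapply(tracks, `[[`, "img")),
             x = unlist(lapply(tracks, `[[`, "x")),
             y = unlist(lapply(tracks, `[[`, "y")))
}

# new empty reconstruction model
new_model <- function(tracks, intr, body, n_images) {
  structure(list(
    tracks = tracks, obs = track_obs(tracks),
    intr = intr, body = as.integer(body), n_images = n_images,
    poses = vector("list", n_images),
    points = matrix(NA_real_, length(tracks), 3),
    dense = NULL, dense_band = NULL, rmse = NA_real_
  ), class = "recon_model")
}

#' @export
print.recon_model <- function(x, ...) {
  cat(sprintf("reconstruction: %d/%d images registered, %d/%d points, RMSE %.3f px\n",
              sum(!vapply(x$poses, is.null, TRUE)), x$n_images,
              sum(!is.na(x$points[, 1])), nrow(x$points), x$rmse))
  invisible(x)
}

#' Ids of the images registered in a reconstruction
#' @param model A `"recon_model"`.
#' @return Integer vector of registered image ids.
#' @export
registered_ids <- function(model)
  which(!vapply(model$poses, is.null, TRUE))

# undistorted normalised coordinates of observation rows for their images
obs_normalised <- function(model, rows) {
  o <- model$obs[rows, , drop = FALSE]
  out <- matrix(NA_real_, nrow(o), 2)
  for (b in unique(model$body[o$img])) {
    sel <- model$body[o$img] == b
    out[sel, ] <- undistort_pixels(cbind(o$x[sel], o$y[sel]), model$intr[[b]])
  }
  out
}

# triangulation angle (degrees): max pairwise ray angle from cams to X
tri_angle <- function(X, centres) {
  d <- sweep(centres, 2, X)
  d <- d / sqrt(rowSums(d^2))
  g <- d %*% t(d)
  acos(min(1, max(-1, min(g[upper.tri(g)])))) * 180 / pi
}

#' Initialise a reconstruction from a two-view seed pair
#'
#' Estimates the relative pose of a seed pair from the essential matrix of
#' their shared track observations (normalised eight-point estimate,
#' singular values forced to (1,1,0)), resolves the four-fold pose
#' ambiguity by cheirality (all triangulated points must lie in front of
#' both cameras), and triangulates the shared tracks.  The first camera
#' defines the reconstruction frame and the baseline its unit of length.
#'
#' @param tracks A [build_tracks()] track graph (or its `tracks` list).
#' @param intr List of [camera_intrinsics()], one per camera body.
#' @param body Integer body index per image id.
#' @param n_images Total number of images.
#' @param pair Optional `c(i, j)` forcing the seed pair; otherwise the
#'   pair maximising shared-track count times median triangulation angle
#'   is chosen.
#' @param min_shared Minimum shared tracks for a candidate seed pair.
#' @param min_angle_deg Minimum median triangulation angle (degrees).
#' @return A partial reconstruction model (class `"recon_model"`).
#' @export
initialize_pair <- function(tracks, intr, body, n_images, pair = NULL,
                            min_shared = 100, min_angle_deg = 1.5) {
  if (inherits(tracks, "track_graph")) tracks <- tracks$tracks
  model <- new_model(tracks, intr, body, n_images)
  obs <- model$obs
  # shared-track counts per pair
  cand_pairs <- if (!is.null(pair)) list(pair) else {
    tab <- list()
    for (t in seq_along(tracks)) {
      im <- tracks[[t]]$img
      if (length(im) < 2) next
      pr <- utils::combn(sort(im), 2)
      for (k in seq_len(ncol(pr))) {
        ky <- paste(pr[1, k], pr[2, k])
        tab[[ky]] <- (tab[[ky]] %||% 0L) + 1L
      }
    }
    cnt <- unlist(tab)
    cnt <- sort(cnt[cnt >= min_shared], decreasing = TRUE)
    if (length(cnt) == 0) stop("no candidate seed pair with enough shared tracks")
    lapply(names(utils::head(cnt, 12)), function(k)
      as.integer(strsplit(k, " ")[[1]]))
  }
  best <- NULL
  for (pr in cand_pairs) {
    res <- try_init_pair(model, pr, min_angle_deg)
    if (is.null(res)) next
    if (is.null(best) || res$score > best$score) best <- res
  }
  if (is.null(best))
    stop("initialization failure: all candidate pairs degenerate (low parallax)")
  best$model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

try_init_pair <- function(model, pr, min_angle_deg) {
  obs <- model$obs
  ta <- obs$track[obs$img == pr[1]]
  tb <- obs$track[obs$img == pr[2]]
  shared <- intersect(ta, tb)
  if (length(shared) < 8) return(NULL)
  rows_a <- which(obs$img == pr[1] & obs$track %in% shared)
  rows_b <- which(obs$img == pr[2] & obs$track %in% shared)
  rows_a <- rows_a[match(shared, obs$track[rows_a])]
  rows_b <- rows_b[match(shared, obs$track[rows_b])]
  na <- obs_normalised(model, rows_a)
  nb <- obs_normalised(model, rows_b)
  E <- tryCatch(essential_from_normalised(na, nb), error = function(e) NULL)
  if (is.null(E)) return(NULL)
  rel <- decompose_essential(E, na, nb)
  if (is.null(rel)) return(NULL)
  poseA <- camera_pose(diag(3), c(0, 0, 0))
  poseB <- camera_pose(rel$R, -as.numeric(t(rel$R) %*% rel$t))
  # triangulate shared tracks
  Rc <- array(c(poseA$R, poseB$R), c(3, 3, 2))
  Cc <- rbind(poseA$centre, poseB$centre)
  tri <- triangulate_points_cpp(
    rep(0:1, each = length(shared)), rep(seq_along(shared) - 1L, 2),
    c(na[, 1], nb[, 1]), c(na[, 2], nb[, 2]), Rc, Cc, length(shared))
  X <- tri$X
  ok <- tri$ok
  # cheirality + angle checks
  ang <- rep(0, length(shared))
  for (i in seq_along(shared)) {
    if (!ok[i]) next
    za <- (poseA$R %*% (X[i, ] - poseA$centre))[3]
    zb <- (poseB$R %*% (X[i, ] - poseB$centre))[3]
    if (za <= 0 || zb <= 0) { ok[i] <- FALSE; next }
    ang[i] <- tri_angle(X[i, ], Cc)
  }
  med_ang <- stats::median(ang[ok])
  if (!is.finite(med_ang) || med_ang < min_angle_deg || sum(ok) < 8)
    return(NULL)
  model$poses[[pr[1]]] <- poseA
  model$poses[[pr[2]]] <- poseB
  model$points[shared[ok], ] <- X[ok, , drop = FALSE]
  list(model = model, score = sum(ok) * med_ang)
}

# essential matrix from normalised coords (8-point + (1,1,0) projection)
essential_from_normalised <- function(na, nb) {
  A <- cbind(nb[, 1] * na[, 1], nb[, 1] * na[, 2], nb[, 1],
             nb[, 2] * na[, 1], nb[, 2] * na[, 2], nb[, 2],
             na[, 1], na[, 2], 1)
  e <- svd(A, nu = 0, nv = 9)$v[, 9]
  E0 <- matrix(e, 3, 3, byrow = TRUE)
  s <- svd(E0)
  s$u %*% diag(c(1, 1, 0)) %*% t(s$v)
}

# four-fold decomposition with cheirality vote
decompose_essential <- function(E, na, nb) {
  s <- svd(E)
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cands <- list(list(R = U %*% W %*% t(V), t = U[, 3]),
                list(R = U %*% W %*% t(V), t = -U[, 3]),
                list(R = U %*% t(W) %*% t(V), t = U[, 3]),
                list(R = U %*% t(W) %*% t(V), t = -U[, 3]))
  nsub <- min(nrow(na), 50)
  idx <- round(seq(1, nrow(na), length.out = nsub))
  best <- NULL; best_cnt <- -1
  for (cd in cands) {
    cnt <- 0
    C2 <- -as.numeric(t(cd$R) %*% cd$t)
    Rc <- array(c(diag(3), cd$R), c(3, 3, 2))
    Cc <- rbind(c(0, 0, 0), C2)
    tri <- triangulate_points_cpp(rep(0:1, each = nsub),
                                  rep(seq_len(nsub) - 1L, 2),
                                  c(na[idx, 1], nb[idx, 1]),
                                  c(na[idx, 2], nb[idx, 2]), Rc, Cc, nsub)
    for (i in seq_len(nsub)) {
      if (!tri$ok[i]) next
      X <- tri$X[i, ]
      if (X[3] > 0 && (cd$R %*% (X - C2))[3] > 0) cnt <- cnt + 1
    }
    if (cnt > best_cnt) { best_cnt <- cnt; best <- cd }
  }
  if (best_cnt < 0.6 * nsub) return(NULL)  # ambiguous / degenerate
  best
}

#' Register one image into the reconstruction
#'
#' Estimates the camera pose of an unregistered image from its 2D
#' observations of already-triangulated tracks by robust
#' perspective-n-point within RANSAC: each hypothesis is a Gauss-Newton
#' pose fit to a minimal sample of correspondences, seeded from the pose
#' of the registered camera sharing the most tracks (a direct-linear
#' minimal solver is degenerate on the near-planar terrain these surveys
#' image, so a seeded local solve is used instead); inliers are counted by
#' reprojection error and the pose is re-refined on all inliers with a
#' Huber loss.  Newly observable tracks are triangulated afterwards by
#' [triangulate_new_points()].
#'
#' @param model A `"recon_model"`.
#' @param img Image id to register.
#' @param reproj_px Inlier/acceptance reprojection threshold (pixels).
#' @param min_correspondences Minimum 2D-3D correspondences required.
#' @param seed RANSAC seed.
#' @param init_pose Optional [camera_pose()] seeding the local solves;
#'   defaults to the registered camera sharing the most tracks.
#' @return Updated model, or `NULL` when the image cannot be registered
#'   (insufficient correspondences or RANSAC failure).
#' @export
register_view <- function(model, img, reproj_px = 4,
                          min_correspondences = 6, seed = 1,
                          init_pose = NULL) {
  if (!is.null(model$poses[[img]]))
    stop("image already registered")
  rows <- which(model$obs$img == img & !is.na(model$points[model$obs$track, 1]))
  if (length(rows) < min_correspondences) return(NULL)
  Xw <- model$points[model$obs$track[rows], , drop = FALSE]
  xn <- obs_normalised(model, rows)
  intr <- model$intr[[model$body[img]]]
  if (is.null(init_pose)) {
    reg <- registered_ids(model)
    shared <- vapply(reg, function(r) {
      length(intersect(model$obs$track[model$obs$img == r],
                       model$obs$track[rows]))
    }, 0L)
    init_pose <- model$poses[[reg[which.max(shared)]]]
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(rows)
  best_in <- NULL; best_cnt <- 0; best_pose <- NULL
  n_iter <- 100
  it <- 0
  while (it < n_iter) {
    it <- it + 1
    s <- sample.int(n, min(8, n))
    ps <- tryCatch(pose_gauss_newton(init_pose, Xw[s, , drop = FALSE],
                                     xn[s, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(ps)) next
    e <- pnp_errors(ps, Xw, xn, intr)
    inl <- e < reproj_px
    if (sum(inl) > best_cnt) {
      best_cnt <- sum(inl); best_in <- inl; best_pose <- ps
      ratio <- max(best_cnt / n, 1e-6)
      n_iter <- min(100, ceiling(log(1e-3) / log(1 - min(ratio^8, 1 - 1e-12))))
    }
  }
  if (best_cnt < min_correspondences) return(NULL)
  ps <- tryCatch(pose_gauss_newton(best_pose, Xw[best_in, , drop = FALSE],
                                   xn[best_in, , drop = FALSE],
                                   huber = reproj_px / intr$focal),
                 error = function(e) NULL)
  if (is.null(ps)) return(NULL)
  e <- pnp_errors(ps, Xw, xn, intr)
  if (stats::median(e[best_in]) > reproj_px) return(NULL)
  model$poses[[img]] <- ps
  model
}

# Gauss-Newton pose fit on normalised coordinates, seeded from init
pose_gauss_newton <- function(init, X, xn, iters = 12, huber = Inf) {
  R <- init$R; C <- init$centre
  n <- nrow(X)
  for (it in seq_len(iters)) {
    Xc <- t(R %*% (t(X) - C))
    z <- Xc[, 3]
    if (any(z <= 1e-9)) stop("point behind camera during pose refinement")
    rx <- Xc[, 1] / z - xn[, 1]
    ry <- Xc[, 2] / z - xn[, 2]
    H <- matrix(0, 6, 6); g <- numeric(6)
    for (i in seq_len(n)) {
      B <- matrix(c(1 / z[i], 0, -Xc[i, 1] / z[i]^2,
                    0, 1 / z[i], -Xc[i, 2] / z[i]^2), 2, 3, byrow = TRUE)
      Jr <- -B %*% skew3(Xc[i, ])
      Jt <- -B %*% R
      Ji <- cbind(Jr, Jt)
      ri <- c(rx[i], ry[i])
      w <- 1
      if (is.finite(huber)) {
        e <- sqrt(sum(ri^2))
        if (e > huber) w <- huber / e
      }
      H <- H + w * crossprod(Ji)
      g <- g + w * crossprod(Ji, ri)
    }
    d <- tryCatch(solve(H + 1e-9 * diag(6), -g), error = function(e) NULL)
    if (is.null(d)) stop("singular pose system")
    R <- rodrigues(d[1:3]) %*% R
    C <- C + d[4:6]
    if (sqrt(sum(d^2)) < 1e-10) break
  }
  camera_pose(R, C)
}

pnp_errors <- function(pose, X, xn, intr) {
  Xc <- t(pose$R %*% (t(X) - pose$centre))
  z <- Xc[, 3]
  err <- sqrt((Xc[, 1] / z - xn[, 1])^2 + (Xc[, 2] / z - xn[, 2])^2) * intr$focal
  err[z <= 0] <- 1e9
  err
}

#' Triangulate tracks that newly have two or more registered views
#'
#' @param model A `"recon_model"`.
#' @param min_angle_deg Minimum triangulation angle.
#' @param reproj_px Maximum mean reprojection error (pixels).
#' @return Updated model.
#' @export
triangulate_new_points <- function(model, min_angle_deg = 2, reproj_px = 4) {
  reg <- registered_ids(model)
  rows <- which(model$obs$img %in% reg & is.na(model$points[model$obs$track, 1]))
  if (length(rows) == 0) return(model)
  tr <- model$obs$track[rows]
  counts <- table(tr)
  good_tracks <- as.integer(names(counts[counts >= 2]))
  rows <- rows[tr %in% good_tracks]
  if (length(rows) == 0) return(model)
  tr <- model$obs$track[rows]
  tid <- match(tr, good_tracks)
  cam_map <- match(model$obs$img[rows], reg)
  xn <- obs_normalised(model, rows)
  Rc <- array(0, c(3, 3, length(reg)))
  Cc <- matrix(0, length(reg), 3)
  for (i in seq_along(reg)) {
    Rc[, , i] <- model$poses[[reg[i]]]$R
    Cc[i, ] <- model$poses[[reg[i]]]$centre
  }
  tri <- triangulate_points_cpp(cam_map - 1L, tid - 1L,
                                xn[, 1], xn[, 2], Rc, Cc, length(good_tracks))
  # validate: cheirality, angle, reprojection
  for (i in seq_along(good_tracks)) {
    if (!tri$ok[i]) next
    X <- tri$X[i, ]
    sel <- which(tid == i)
    cams <- cam_map[sel]
    z <- vapply(cams, function(c) (Rc[, , c] %*% (X - Cc[c, ]))[3], 0)
    if (any(z <= 0)) next
    if (tri_angle(X, Cc[cams, , drop = FALSE]) < min_angle_deg) next
    e <- vapply(seq_along(sel), function(k) {
      Xc <- Rc[, , cams[k]] %*% (X - Cc[cams[k], ])
      sqrt(sum((Xc[1:2] / Xc[3] - xn[sel[k], ])^2))
    }, 0) * model$intr[[1]]$focal
    if (mean(e) > reproj_px) next
    model$points[good_tracks[i], ] <- X
  }
  model
}

#' Bundle adjustment
#'
#' Joint nonlinear refinement of all registered camera poses, triangulated
#' points and the shared intrinsics of each camera body (focal length and
#' two radial distortion coefficients; principal point fixed at the image
#' centre), minimising Huber-robustified reprojection error by
#' Levenberg-Marquardt with a Schur complement on the point blocks.  The
#' gauge is fixed by holding the first registered camera constant; the
#' accepted objective is non-increasing by construction.
#'
#' @param model A `"recon_model"`.
#' @param huber_px Huber loss scale (pixels).
#' @param max_iter Maximum accepted LM iterations.
#' @param fit_intrinsics Refine intrinsics (self-calibration)?
#' @param fix_gauge Hold the first registered camera fixed.
#' @param focal_prior Optional numeric vector (one nominal focal length
#'   per body, pixels) adding a soft prior on the focal estimate;
#'   near-planar nadir surveys make focal weakly observable, and the
#'   prior (far weaker than real image evidence) prevents collapse into
#'   the focal/height ambiguity.
#' @param focal_prior_sd_frac Prior standard deviation as a fraction of
#'   the nominal focal.
#' @return Updated model with `rmse` (unweighted reprojection RMSE, px)
#'   and attribute `"cost_trace"` on the model.
#' @export
bundle_adjust <- function(model, huber_px = 2, max_iter = 30,
                          fit_intrinsics = TRUE, fix_gauge = TRUE,
                          focal_prior = NULL, focal_prior_sd_frac = 0.1) {
  reg <- registered_ids(model)
  if (length(reg) < 2) stop("bundle adjustment needs at least 2 registered views")
  valid <- which(!is.na(model$points[, 1]))
  rows <- which(model$obs$img %in% reg & model$obs$track %in% valid)
  cam_map <- match(model$obs$img[rows], reg)
  pt_map <- match(model$obs$track[rows], valid)
  Rc <- array(0, c(3, 3, length(reg)))
  Cc <- matrix(0, length(reg), 3)
  for (i in seq_along(reg)) {
    Rc[, , i] <- model$poses[[reg[i]]]$R
    Cc[i, ] <- model$poses[[reg[i]]]$centre
  }
  intr_mat <- t(vapply(model$intr, function(ii)
    c(ii$focal, ii$cx, ii$cy, ii$k1, ii$k2), numeric(5)))
  fit <- bundle_adjust_cpp(Rc, Cc, model$body[reg] - 1L, intr_mat,
                           model$points[valid, , drop = FALSE],
                           cam_map - 1L, pt_map - 1L,
                           model$obs$x[rows], model$obs$y[rows],
                           if (fix_gauge) 0L else integer(0),
                           fit_intrinsics, huber_px, max_iter,
                           1e-3, 1e-8,
                           focal_prior,
                           if (is.null(focal_prior)) 0
                           else focal_prior_sd_frac * mean(focal_prior))
  for (i in seq_along(reg))
    model$poses[[reg[i]]] <- camera_pose(fit$R[, , i], fit$C[i, ])
  for (b in seq_along(model$intr)) {
    model$intr[[b]]$focal <- fit$intr[b, 1]
    model$intr[[b]]$k1 <- fit$intr[b, 4]
    model$intr[[b]]$k2 <- fit$intr[b, 5]
  }
  model$points[valid, ] <- fit$pts
  model$rmse <- fit$rmse
  attr(model, "cost_trace") <- fit$cost_trace
  model
}

# drop points failing reprojection / angle / cheirality tests
prune_points <- function(model, reproj_px = 4, min_angle_deg = 2) {
  reg <- registered_ids(model)
  valid <- which(!is.na(model$points[, 1]))
  if (length(valid) == 0) return(model)
  rows <- which(model$obs$img %in% reg & model$obs$track %in% valid)
  cam_map <- match(model$obs$img[rows], reg)
  pt_map <- match(model$obs$track[rows], valid)
  Rc <- array(0, c(3, 3, length(reg)))
  Cc <- matrix(0, length(reg), 3)
  for (i in seq_along(reg)) {
    Rc[, , i] <- model$poses[[reg[i]]]$R
    Cc[i, ] <- model$poses[[reg[i]]]$centre
  }
  intr_mat <- t(vapply(model$intr, function(ii)
    c(ii$focal, ii$cx, ii$cy, ii$k1, ii$k2), numeric(5)))
  rp <- reproject_cpp(cam_map - 1L, pt_map - 1L,
                      model$obs$x[rows], model$obs$y[rows],
                      Rc, Cc, model$body[reg] - 1L, intr_mat,
                      model$points[valid, , drop = FALSE])
  bad_depth <- tapply(rp$depth <= 0, pt_map, any)
  mean_err <- tapply(rp$err, pt_map, mean)
  n_obs <- tapply(rp$err, pt_map, length)
  drop <- as.integer(names(mean_err))[mean_err > reproj_px | bad_depth |
                                        n_obs < 2]
  # angle check
  keep <- setdiff(seq_along(valid), drop)
  for (i in keep) {
    sel <- which(pt_map == i)
    cams <- unique(cam_map[sel])
    if (length(cams) < 2 ||
        tri_angle(model$points[valid[i], ], Cc[cams, , drop = FALSE]) < min_angle_deg)
      drop <- c(drop, i)
  }
  if (length(drop)) model$points[valid[drop], ] <- NA_real_
  model
}

#' Run incremental structure-from-motion
#'
#' Full incremental loop: seed-pair initialisation, repeated
#' [register_view()] of the unregistered image with the most 2D-3D
#' correspondences, triangulation of new tracks, periodic
#' [bundle_adjust()] and outlier-point pruning, until no image can be
#' added; then final bundle adjustment.
#'
#' @param tracks A [build_tracks()] track graph.
#' @param intr List of initial [camera_intrinsics()] per body (nominal
#'   focal guess; refined by self-calibration).
#' @param body Integer body index per image id (1 = colour, 2 = NIR).
#' @param n_images Number of images.
#' @param seed Seed governing all RANSAC draws.
#' @param ba_every Bundle-adjust after this many new registrations.
#' @param min_tri_angle_deg,huber_px,prune_px Geometric thresholds.
#' @param verbose Print progress.
#' @return A `"recon_model"` with all registrable images placed.
#' @export
run_incremental_sfm <- function(tracks, intr, body, n_images, seed = 1,
                                ba_every = 4, min_tri_angle_deg = 2,
                                huber_px = 2, prune_px = 4,
                                verbose = FALSE) {
  if (n_images < 2) stop("need at least 2 images")
  fprior <- vapply(intr, `[[`, 0, "focal")
  model <- initialize_pair(tracks, intr, body, n_images,
                           min_angle_deg = min_tri_angle_deg / 2)
  model <- triangulate_new_points(model, min_tri_angle_deg, prune_px)
  # intrinsics stay at their nominal prior during incremental growth;
  # freeing them with only a few near-nadir views lets the focal/height
  # ambiguity of near-planar scenes pick a wrong basin that later views
  # cannot escape.  Self-calibration happens in the final adjustments.
  model <- bundle_adjust(model, huber_px, fit_intrinsics = FALSE)
  since_ba <- 0L
  skipped <- integer(0)
  repeat {
    unreg <- setdiff(seq_len(n_images), c(registered_ids(model), skipped))
    if (length(unreg) == 0) break
    # most 2D-3D correspondences first
    valid_tracks <- which(!is.na(model$points[, 1]))
    n2d3d <- vapply(unreg, function(im)
      sum(model$obs$img == im & model$obs$track %in% valid_tracks), 0L)
    if (max(n2d3d) < 6) break
    img <- unreg[which.max(n2d3d)]
    m2 <- register_view(model, img, reproj_px = prune_px,
                        seed = seed + img)
    if (is.null(m2)) {
      skipped <- c(skipped, img)
      if (verbose) message("image ", img, " skipped")
      next
    }
    skipped <- integer(0)  # new geometry may rescue earlier failures
    model <- triangulate_new_points(m2, min_tri_angle_deg, prune_px)
    since_ba <- since_ba + 1L
    if (since_ba >= ba_every) {
      model <- bundle_adjust(model, huber_px, fit_intrinsics = FALSE)
      model <- prune_points(model, prune_px, min_tri_angle_deg)
      model <- triangulate_new_points(model, min_tri_angle_deg, prune_px)
      since_ba <- 0L
    }
    if (verbose)
      message(sprintf("registered %d (%d/%d), rmse %.2f px", img,
                      length(registered_ids(model)), n_images, model$rmse))
  }
  model <- bundle_adjust(model, huber_px, max_iter = 50,
                         focal_prior = fprior)
  model <- prune_points(model, prune_px, min_tri_angle_deg)
  model <- bundle_adjust(model, huber_px, max_iter = 50,
                         focal_prior = fprior)
  model
}

#' Align a reconstruction to ground-truth poses by similarity fit
#'
#' Gauge alignment for evaluation: fits the similarity transform mapping
#' reconstructed camera centres to true centres (Horn with scale) and
#' returns the transformed model plus camera-centre errors.
#'
#' @param model A `"recon_model"`.
#' @param true_poses List of true [camera_pose()]s (by image id).
#' @return List: `model` (aligned), `transform`, `centre_errors` (metres,
#'   per registered camera), `rmse`.
#' @export
align_to_truth <- function(model, true_poses) {
  reg <- registered_ids(model)
  est <- t(vapply(reg, function(i) model$poses[[i]]$centre, numeric(3)))
  tru <- t(vapply(reg, function(i) true_poses[[i]]$centre, numeric(3)))
  tf <- horn_align(est, tru, estimate_scale_flag = TRUE)
  aligned <- transform_model(model, tf)
  err <- sqrt(rowSums((t(vapply(reg, function(i) aligned$poses[[i]]$centre,
                                numeric(3))) - tru)^2))
  list(model = aligned, transform = tf, centre_errors = err,
       rmse = sqrt(mean(err^2)))
}
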