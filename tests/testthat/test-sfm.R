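# synthetic multi-view geometry with exact observations, no rendering
make_geom <- function(n_pts = 300, n_cams = 3, seed = 31, distort = FALSE) {
  set.seed(seed)
  intr <- camera_intrinsics(focal = 436, width = 640, height = 480,
                            k1 = if (distort) -0.05 else 0,
                            k2 = if (distort) 0.008 else 0)
  poses <- lapply(seq_len(n_cams), function(i)
    camera_pose(rodrigues(rnorm(3, 0, 0.03)) %*%
                  nadir_pose(c(8 + 3 * i, 11 + (i %% 2), 15 + 0.2 * i))$R,
                c(8 + 3 * i, 11 + (i %% 2), 15 + 0.2 * i)))
  X <- cbind(runif(n_pts, 5, 25), runif(n_pts, 4, 18), runif(n_pts, -1, 2))
  tracks <- list()
  for (p in seq_len(n_pts)) {
    img <- c(); x <- c(); y <- c()
    for (i in seq_len(n_cams)) {
      px <- project_points(X[p, ], poses[[i]], intr)
      if (is.na(px[1, 1]) || px[1, 1] < 5 || px[1, 1] > 634 ||
          px[1, 2] < 5 || px[1, 2] > 474) next
      img <- c(img, i); x <- c(x, px[1, 1]); y <- c(y, px[1, 2])
    }
    if (length(img) >= 2)
      tracks[[length(tracks) + 1]] <-
        data.frame(img = img, kp = p, x = x, y = y)
  }
  list(tracks = tracks, poses = poses, intr = intr, X = X)
}

test_that("two-view initialisation recovers the true relative pose", {
  g <- make_geom(n_pts = 300, n_cams = 2, seed = 31)
  model <- initialize_pair(g$tracks, list(g$intr), rep(1L, 2), 2,
                           pair = c(1, 2))
  # compare relative rotation (gauge: first camera at identity)
  R_rel_true <- g$poses[[2]]$R %*% t(g$poses[[1]]$R)
  R_rel_est <- model$poses[[2]]$R %*% t(model$poses[[1]]$R)
  ang <- acos(min(1, (sum(diag(R_rel_est %*% t(R_rel_true))) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)
  # translation direction (scale is free)
  t_true <- g$poses[[1]]$R %*% (g$poses[[2]]$centre - g$poses[[1]]$centre)
  t_est <- model$poses[[1]]$R %*%
    (model$poses[[2]]$centre - model$poses[[1]]$centre)
  cosang <- sum(t_true * t_est) / sqrt(sum(t_true^2) * sum(t_est^2))
  expect_lt(acos(min(1, abs(cosang))) * 180 / pi, 0.1)
  # cheirality: all triangulated points in front of both cameras
  valid <- which(!is.na(model$points[, 1]))
  for (i in 1:2) {
    Xc <- t(model$poses[[i]]$R %*%
              (t(model$points[valid, ]) - model$poses[[i]]$centre))
    expect_true(all(Xc[, 3] > 0))
  }
})

test_that("a zero-baseline pair is rejected for parallax", {
  set.seed(32)
  intr <- camera_intrinsics(focal = 436, width = 640, height = 480)
  pose1 <- nadir_pose(c(10, 10, 15))
  pose2 <- camera_pose(rodrigues(c(0, 0, 0.1)) %*% pose1$R, pose1$centre)
  X <- cbind(runif(200, 5, 15), runif(200, 5, 15), runif(200, -1, 1))
  tracks <- list()
  for (p in 1:200) {
    a <- project_points(X[p, ], pose1, intr)
    b <- project_points(X[p, ], pose2, intr)
    if (anyNA(c(a, b))) next
    tracks[[length(tracks) + 1]] <-
      data.frame(img = 1:2, kp = p, x = c(a[1], b[1]), y = c(a[2], b[2]))
  }
  expect_error(initialize_pair(tracks, list(intr), rep(1L, 2), 2,
                               pair = c(1, 2)),
               "degenerate|parallax|failure")
})

test_that("view registration recovers a known third pose and is guarded", {
  g <- make_geom(n_pts = 400, n_cams = 3, seed = 33)
  model <- initialize_pair(g$tracks, list(g$intr), rep(1L, 3), 3,
                           pair = c(1, 2))
  model <- triangulate_new_points(model)
  model <- register_view(model, 3, seed = 7)
  expect_false(is.null(model))
  # gauge-align and compare the third camera centre to truth
  al <- align_to_truth(model, g$poses)
  expect_lt(max(al$centre_errors), 0.01 * 15)  # well under 1% of height
  expect_error(register_view(model, 3), "already registered")
})

test_that("an image with no triangulated-track overlap is skipped", {
  g <- make_geom(n_pts = 300, n_cams = 2, seed = 34)
  model <- initialize_pair(g$tracks, list(g$intr), rep(1L, 3), 3,
                           pair = c(1, 2))
  expect_null(register_view(model, 3, seed = 1))
})

test_that("bundle adjustment has a fixed point and non-increasing cost", {
  g <- make_geom(n_pts = 250, n_cams = 3, seed = 35)
  model <- initialize_pair(g$tracks, list(g$intr), rep(1L, 3), 3,
                           pair = c(1, 2))
  model <- triangulate_new_points(model)
  model <- register_view(model, 3, seed = 2)
  m1 <- bundle_adjust(model, fit_intrinsics = FALSE)
  tr <- attr(m1, "cost_trace")
  expect_true(all(diff(tr) <= 1e-12))
  expect_lt(m1$rmse, 0.05)
  # already at optimum: poses should barely move
  m2 <- bundle_adjust(m1, fit_intrinsics = FALSE)
  expect_lt(max(abs(m2$poses[[2]]$centre - m1$poses[[2]]$centre)), 1e-6)
})

test_that("bundle adjustment repairs a perturbed model", {
  g <- make_geom(n_pts = 250, n_cams = 3, seed = 36)
  model <- initialize_pair(g$tracks, list(g$intr), rep(1L, 3), 3,
                           pair = c(1, 2))
  model <- triangulate_new_points(model)
  model <- register_view(model, 3, seed = 3)
  model <- bundle_adjust(model, fit_intrinsics = FALSE)
  # perturb: ~1 degree pose noise, 1% point noise
  set.seed(9)
  pert <- model
  for (i in 2:3) {
    p <- pert$poses[[i]]
    pert$poses[[i]] <- camera_pose(rodrigues(rnorm(3, 0, 0.017 / sqrt(3))) %*% p$R,
                                   p$centre + rnorm(3, 0, 0.05))
  }
  valid <- !is.na(pert$points[, 1])
  pert$points[valid, ] <- pert$points[valid, ] *
    (1 + matrix(rnorm(sum(valid) * 3, 0, 0.01), sum(valid), 3))
  fixed <- bundle_adjust(pert, fit_intrinsics = FALSE, max_iter = 60)
  expect_lt(fixed$rmse, 0.3)
})

test_that("incremental SfM on rendered views is accurate and deterministic", {
  m <- small_model()
  s <- m
  expect_equal(length(registered_ids(m$model)), length(s$feats))
  expect_lt(m$model$rmse, 1)
  al <- align_to_truth(m$model, s$plan$poses)
  expect_lt(al$rmse, 0.01 * 15)
  # similarity-gauge freedom: transforming the model changes nothing
  # observable (reprojection errors identical)
  tf <- similarity_transform(2.3, random_rotation(), c(4, -2, 7))
  mt <- transform_model(m$model, tf)
  expect_equal(mt$rmse, m$model$rmse)
  reg <- registered_ids(m$model)
  rows <- which(mt$obs$img %in% reg & !is.na(mt$points[mt$obs$track, 1]))
  r1 <- shoremapper:::pnp_errors(mt$poses[[reg[1]]],
                                 mt$points[mt$obs$track[rows[1:50]], ],
                                 shoremapper:::obs_normalised(mt, rows[1:50]),
                                 mt$intr[[1]])
  r0 <- shoremapper:::pnp_errors(m$model$poses[[reg[1]]],
                                 m$model$points[m$model$obs$track[rows[1:50]], ],
                                 shoremapper:::obs_normalised(m$model, rows[1:50]),
                                 m$model$intr[[1]])
  expect_equal(r1, r0, tolerance = 1e-6)
})
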