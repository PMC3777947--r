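test_that("scale estimation is the mean measured/reconstructed edge ratio", {
  tri <- function(side, centre = c(0, 0, 0)) {
    r <- side / sqrt(3)
    t(sapply(c(0, 2, 4) * pi / 3, function(a)
      centre + c(r * cos(a), r * sin(a), 0)))
  }
  g1 <- data.frame(id = 1:3, triad_id = 1, edge_m = 2,
                   rx = tri(0.5)[, 1], ry = tri(0.5)[, 2], rz = tri(0.5)[, 3])
  expect_equal(as.numeric(estimate_scale(g1)), 4.0)
  g2 <- rbind(g1, data.frame(id = 4:6, triad_id = 2, edge_m = 2,
                             rx = tri(1, c(5, 5, 0))[, 1],
                             ry = tri(1, c(5, 5, 0))[, 2],
                             rz = tri(1, c(5, 5, 0))[, 3]))
  expect_equal(as.numeric(estimate_scale(g2)), 3.0)  # mean of {4,4,4,2,2,2}
  g1$rx <- g1$rx * 0
  g1$ry <- g1$ry * 0
  expect_error(estimate_scale(g1), "zero-length")
})

test_that("Horn alignment is exact on identity and random similarities", {
  set.seed(41)
  X <- matrix(runif(30, -5, 5), 10, 3)
  tf <- horn_align(X, X)
  expect_equal(tf$scale, 1)
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_lt(max(attr(tf, "residuals")), 1e-12)
  for (i in 1:25) {
    s <- runif(1, 0.2, 5)
    R <- random_rotation()
    t <- runif(3, -10, 10)
    Y <- s * t(R %*% t(X)) + matrix(t, 10, 3, byrow = TRUE)
    tf <- horn_align(X, Y, estimate_scale_flag = TRUE)
    expect_equal(tf$scale, s, tolerance = 1e-9)
    expect_lt(max(abs(tf$R - R)), 1e-9)
    expect_lt(max(attr(tf, "residuals")), 1e-9)
  }
  expect_error(horn_align(matrix(rep(1:3, 3), 3, 3, byrow = TRUE) *
                            c(1, 2, 3), X[1:3, ] * 0 + 1:3), "degenerate")
})

test_that("Horn residual matches a brute-force rotation-space search", {
  set.seed(42)
  for (i in 1:3) {
    src <- matrix(runif(9, -3, 3), 3, 3)
    tgt <- matrix(runif(9, -3, 3), 3, 3)
    tf <- horn_align(src, tgt)
    horn_rms <- sqrt(mean(attr(tf, "residuals")^2))
    oracle_rms <- oracle_align_residual(src, tgt, seed = i)
    expect_lt(abs(horn_rms - oracle_rms), 1e-3)
  }
})

test_that("Horn solution is a global optimum under rotation perturbation", {
  set.seed(43)
  X <- matrix(runif(24, -4, 4), 8, 3)
  R <- random_rotation()
  Y <- t(R %*% t(X)) + matrix(c(1, 2, 3), 8, 3, byrow = TRUE) +
    matrix(rnorm(24, 0, 0.1), 8, 3)
  tf <- horn_align(X, Y)
  base <- sum(attr(tf, "residuals")^2)
  sc <- colMeans(X); tc <- colMeans(Y)
  for (i in 1:1000) {
    w <- rnorm(3); w <- w / sqrt(sum(w^2)) * runif(1, 0, 5 * pi / 180)
    Rp <- rodrigues(w) %*% tf$R
    tp <- tc - as.numeric(Rp %*% sc)
    r <- sum((t(Rp %*% t(X)) + matrix(tp, 8, 3, byrow = TRUE) - Y)^2)
    expect_gte(r, base - 1e-12)
  }
})

test_that("similarity transforms compose and invert to round-trip", {
  set.seed(44)
  tf <- similarity_transform(2.5, random_rotation(), c(3, -1, 2))
  X <- matrix(runif(30, -5, 5), 10, 3)
  back <- apply_similarity(invert_similarity(tf), apply_similarity(tf, X))
  expect_equal(back, X, tolerance = 1e-9)
  tf2 <- similarity_transform(0.5, random_rotation(), c(-2, 0, 1))
  expect_equal(apply_similarity(compose_similarity(tf2, tf), X),
               apply_similarity(tf2, apply_similarity(tf, X)),
               tolerance = 1e-9)
})

# exact synthetic geo-registration setup: reconstruction frame is a known
# similarity of the world
exact_georef_case <- function(scene, gps_noise, seed) {
  set.seed(seed)
  gc <- place_gcps(scene, 3, 2, gps_noise_sd_m = gps_noise, seed = seed)
  tf_world2recon <- similarity_transform(1 / 3.7, random_rotation(),
                                         c(2, -1, 0.5))
  rec <- apply_similarity(tf_world2recon,
                          as.matrix(gc$truth[, c("x", "y", "z")]))
  gcps <- gc$gcps
  gcps$rx <- rec[, 1]; gcps$ry <- rec[, 2]; gcps$rz <- rec[, 3]
  list(gcps = gcps, truth = gc$truth, tf = tf_world2recon)
}

test_that("geo-registration decouples local from global accuracy", {
  scene <- generate_scene(seed = 2)
  # zero GPS noise: both residuals vanish and scale is exact
  cs <- exact_georef_case(scene, 0, 51)
  geo <- georegister(NULL, cs$gcps, scene$geodetic_origin)
  expect_lt(geo$report$global_residual_m, 1e-6)
  expect_lt(geo$report$local_residual_m, 1e-6)
  expect_equal(geo$report$scale * cs$tf$scale, 1, tolerance = 1e-6)
  # Monte-Carlo with 1.2 m GPS noise: the local (edge-length) residual is
  # untouched while the global residual tracks the noise magnitude
  glob <- loc <- c()
  for (s in 1:12) {
    cs <- exact_georef_case(scene, 1.2, 60 + s)
    geo <- georegister(NULL, cs$gcps, scene$geodetic_origin)
    glob <- c(glob, geo$report$global_residual_m)
    loc <- c(loc, geo$report$local_residual_m)
  }
  expect_true(all(loc < 1e-3))          # < 1 mm
  expect_gt(mean(glob), 0.4)            # same order as the GPS noise
  expect_lt(mean(glob), 3.6)
})

test_that("the waterline datum correction is a rigid vertical shift", {
  set.seed(52)
  pts <- matrix(runif(30, 0, 10), 10, 3)
  model <- list(points = pts, dense = pts + 1,
                poses = list(nadir_pose(c(5, 5, 15))))
  wl <- cbind(runif(20, 0, 10), runif(20, 0, 10), rnorm(20, 1.5, 0.01))
  adj <- adjust_vertical_datum(model, wl, 0.16)
  expect_equal(adj$shift_m, 0.16 - mean(wl[, 3]), tolerance = 1e-12)
  expect_equal(adj$model$points[, 3], pts[, 3] + adj$shift_m)
  expect_equal(adj$model$points[, 1:2], pts[, 1:2])
  # pairwise distances unchanged
  expect_equal(as.vector(dist(adj$model$points)), as.vector(dist(pts)),
               tolerance = 1e-12)
  # already-correct model: zero shift
  wl0 <- wl; wl0[, 3] <- 0.16
  expect_equal(adjust_vertical_datum(model, wl0, 0.16)$shift_m, 0,
               tolerance = 1e-12)
  expect_warning(adjust_vertical_datum(model, wl[0, ], 0.16), "empty")
})
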