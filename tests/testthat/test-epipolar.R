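# build noiseless correspondences from a known two-view geometry
make_correspondences <- function(n = 200, seed = 21) {
  set.seed(seed)
  intr <- camera_intrinsics(focal = 436, width = 640, height = 480)
  K <- matrix(c(436, 0, 0, 0, 436, 0, intr$cx, intr$cy, 1), 3, 3)
  p1 <- nadir_pose(c(10, 10, 15), yaw_rad = 0.05)
  p2 <- camera_pose(rodrigues(c(0.02, -0.03, 0.01)) %*%
                      nadir_pose(c(13, 11, 15.4))$R, c(13, 11, 15.4))
  X <- cbind(runif(n, 4, 19), runif(n, 5, 16), runif(n, -1, 2))
  a <- project_points(X, p1, intr)
  b <- project_points(X, p2, intr)
  keep <- rowSums(is.na(cbind(a, b))) == 0 &
    a[, 1] > 0 & a[, 1] < 639 & a[, 2] > 0 & a[, 2] < 479 &
    b[, 1] > 0 & b[, 1] < 639 & b[, 2] > 0 & b[, 2] < 479
  list(a = a[keep, ], b = b[keep, ], K = K, p1 = p1, p2 = p2)
}

as_featureset <- function(kp, id) {
  structure(list(id = id, keypoints = kp,
                 descriptors = matrix(0, nrow(kp), 128),
                 response = rep(1, nrow(kp))), class = "feature_set")
}

test_that("noiseless correspondences recover the true fundamental matrix", {
  cc <- make_correspondences()
  F_true <- oracle_fundamental(cc$p1$R, cc$p1$centre, cc$p2$R, cc$p2$centre,
                               cc$K)
  n <- nrow(cc$a)
  cand <- data.frame(idx_a = seq_len(n), idx_b = seq_len(n), dist = 0)
  pm <- filter_epipolar(cand, as_featureset(cc$a, 1), as_featureset(cc$b, 2),
                        threshold_px = 1, seed = 3)
  expect_equal(pm$status, "matched")
  expect_true(all(pm$inlier))
  expect_lt(frob_dist_f(pm$F, F_true), 1e-6)
  # every reported inlier satisfies the Sampson threshold directly
  d <- sampson_distance(pm$F, cc$a, cc$b)
  expect_true(all(d[pm$inlier] < 1))
})

test_that("30% gross outliers are rejected with high recall and precision", {
  cc <- make_correspondences(n = 400, seed = 22)
  n <- nrow(cc$a)
  set.seed(9)
  n_out <- round(0.3 * n)
  out_idx <- sample.int(n, n_out)
  b <- cc$b
  b[out_idx, ] <- cbind(runif(n_out, 0, 639), runif(n_out, 0, 479))
  # geometric ground truth: injected pairs landing on the true epipolar
  # line are valid matches
  F_true <- oracle_fundamental(cc$p1$R, cc$p1$centre, cc$p2$R, cc$p2$centre,
                               cc$K)
  truth_inlier <- sampson_distance(F_true, cc$a, b) < 1
  cand <- data.frame(idx_a = seq_len(n), idx_b = seq_len(n), dist = 0)
  pm <- filter_epipolar(cand, as_featureset(cc$a, 1), as_featureset(b, 2),
                        threshold_px = 1, seed = 4)
  expect_equal(pm$status, "matched")
  recall <- sum(pm$inlier & truth_inlier) / sum(truth_inlier)
  precision <- sum(pm$inlier & truth_inlier) / sum(pm$inlier)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.99)
})

test_that("epipolar filtering is deterministic given the seed", {
  cc <- make_correspondences(n = 300, seed = 23)
  n <- nrow(cc$a)
  cand <- data.frame(idx_a = seq_len(n), idx_b = seq_len(n), dist = 0)
  fa <- as_featureset(cc$a, 1); fb <- as_featureset(cc$b, 2)
  pm1 <- filter_epipolar(cand, fa, fb, 1, seed = 5)
  pm2 <- filter_epipolar(cand, fa, fb, 1, seed = 5)
  expect_identical(pm1$F, pm2$F)
  expect_identical(pm1$inlier, pm2$inlier)
})

test_that("fewer than 8 candidates leaves the pair unmatched", {
  cc <- make_correspondences()
  cand <- data.frame(idx_a = 1:5, idx_b = 1:5, dist = 0)
  pm <- filter_epipolar(cand, as_featureset(cc$a, 1),
                        as_featureset(cc$b, 2), 1, seed = 1)
  expect_equal(pm$status, "unmatched")
  expect_false(any(pm$inlier))
})

test_that("the estimated F has rank 2", {
  cc <- make_correspondences(n = 100, seed = 25)
  Fm <- eight_point(cc$a, cc$b)
  expect_equal(svd(Fm)$d[3], 0, tolerance = 1e-12)
  expect_equal(sum(Fm^2), 1, tolerance = 1e-12)
})
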