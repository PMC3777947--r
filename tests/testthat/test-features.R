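test_that("constant images yield an empty feature set with a warning", {
  img <- matrix(0.5, 100, 120)
  expect_warning(fs <- extract_features(img, 1), "featureless")
  expect_equal(nrow(fs$keypoints), 0)
})

test_that("feature extraction is deterministic and well-formed", {
  s <- small_survey()
  f1 <- extract_features(s$views$images[[1]], 1)
  f2 <- extract_features(s$views$images[[1]], 1)
  expect_identical(f1$keypoints, f2$keypoints)
  expect_identical(f1$descriptors, f2$descriptors)
  # at least 1000 features on a textured synthetic view at survey altitude
  expect_gte(nrow(f1$keypoints), 1000)
  # keypoints inside image bounds; unit descriptors
  expect_true(all(f1$keypoints[, 1] >= 0 &
                    f1$keypoints[, 1] <= ncol(s$views$images[[1]]) - 1))
  norms <- sqrt(rowSums(f1$descriptors^2))
  expect_true(all(abs(norms - 1) < 1e-6))
})

test_that("matching a feature set against itself is the identity", {
  s <- small_survey()
  f <- s$feats[[1]]
  m <- match_pair(f, f, ratio = 0.99)
  expect_true(all(m$idx_a == m$idx_b))
  expect_gt(nrow(m), 0.9 * nrow(f$keypoints))
  # ratio -> 0 kills everything
  expect_equal(nrow(match_pair(f, s$feats[[2]], ratio = 1e-6)), 0)
})

test_that("matching is symmetric", {
  s <- small_survey()
  m_ab <- match_pair(s$feats[[1]], s$feats[[2]])
  m_ba <- match_pair(s$feats[[2]], s$feats[[1]])
  ab <- paste(m_ab$idx_a, m_ab$idx_b)
  ba <- paste(m_ba$idx_b, m_ba$idx_a)
  expect_setequal(ab, ba)
})

test_that("candidate matches between overlapping views follow true geometry", {
  s <- small_survey()
  cand <- match_pair(s$feats[[1]], s$feats[[2]])
  expect_gt(nrow(cand), 100)
  sc <- s$scene; intr <- s$intr
  p1 <- s$plan$poses[[1]]; p2 <- s$plan$poses[[2]]
  xy <- undistort_pixels(s$feats[[1]]$keypoints[cand$idx_a, , drop = FALSE], intr)
  d <- t(p1$R) %*% rbind(t(xy), 1)
  z <- rep(mean(sc$heightfield), ncol(d)); x <- y <- numeric(ncol(d))
  for (it in 1:15) {
    tt <- (z - p1$centre[3]) / d[3, ]
    x <- p1$centre[1] + tt * d[1, ]; y <- p1$centre[2] + tt * d[2, ]
    z <- scene_elevation(sc, x, y)
  }
  px2 <- project_points(cbind(x, y, z), p2, intr)
  err <- sqrt(rowSums((px2 - s$feats[[2]]$keypoints[cand$idx_b, , drop = FALSE])^2))
  expect_gte(mean(err < 2, na.rm = TRUE), 0.9)
})

test_that("colour and near-infrared views of one scene match across bands", {
  s <- small_survey()
  plan_n <- plan_flight(s$scene, 15, 0.7, s$intr, n_rows = 2, seed = 33)
  vn <- render_views(s$scene, plan_n, s$intr, band = "nir", exposure = 2,
                     seed = 11)
  fn <- extract_features(vn$images[[1]], 99)
  cand <- match_pair(s$feats[[1]], fn)
  pm <- filter_epipolar(cand, s$feats[[1]], fn, 2, seed = 8)
  expect_equal(pm$status, "matched")
  expect_gt(sum(pm$inlier), 100)
})
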