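test_that("noise-free flat-scene nadir pixels equal the analytic integral", {
  sc <- generate_scene(size_m = c(20, 12), n_classes = 1, seed = 2)
  sc$heightfield[] <- 0.5
  sc$coverage[] <- "uniform"
  intr <- camera_intrinsics(focal = 400, width = 64, height = 48)
  plan <- structure(list(poses = list(nadir_pose(c(10, 6, 15.5))),
                         altitude_m = 15, footprint_m = c(2.4, 1.8),
                         overlap = 0, intr = intr), class = "flight_plan")
  responses <- default_camera_responses()
  vs <- render_views(sc, plan, intr, responses, "colour",
                     noise_sd = 0, tex_amp = 0)
  expected <- predict_band_response(sc$class_spectra$uniform,
                                    responses$red)$value
  got <- vs$images[[1]][, , 1]
  expect_lt(max(abs(got - expected)) / expected, 1e-6)
})

test_that("rendering is deterministic and validates poses", {
  f <- flat_two_view()
  vs2 <- render_views(f$scene,
                      structure(list(poses = f$poses, intr = f$intr),
                                class = "flight_plan"),
                      f$intr, band = "colour", seed = 9)
  expect_identical(f$views$images[[1]], vs2$images[[1]])
  below <- structure(list(poses = list(nadir_pose(c(10, 6, -5))),
                          intr = f$intr), class = "flight_plan")
  expect_error(render_views(f$scene, below, f$intr, band = "colour"),
               "below the terrain")
})

test_that("rendered geometry matches the hand-computed pinhole projection", {
  # scene split into two classes at a known easting; the renderer must
  # place the boundary where direct projection-equation evaluation says
  sc <- generate_scene(size_m = c(20, 12), n_classes = 1, seed = 2)
  sc$heightfield[] <- 0
  split_x <- 10.3
  xs <- (seq_len(ncol(sc$coverage)) - 1) * sc$cell_m
  sc$coverage <- matrix(ifelse(rep(xs, each = nrow(sc$coverage)) < split_x,
                               "uniform", "water"),
                        nrow(sc$coverage))
  sc$classes <- c("uniform", "water")
  sc$class_spectra$water <- spectrum(seq(400, 800, 5), rep(0.05, 81))
  intr <- camera_intrinsics(focal = 400, width = 320, height = 240,
                            k1 = -0.06, k2 = 0.008)
  pose <- nadir_pose(c(10, 6, 15))
  plan <- structure(list(poses = list(pose), intr = intr),
                    class = "flight_plan")
  vs <- render_views(sc, plan, intr, band = "colour", noise_sd = 0,
                     tex_amp = 0)
  row <- vs$images[[1]][120, , 1]
  edge_col <- which(diff(row < mean(range(row))) != 0)[1]
  px <- oracle_project(c(split_x, 6, 0), pose$R, pose$centre,
                       intr$focal, intr$cx, intr$cy, intr$k1, intr$k2)
  expect_lt(abs(edge_col - 1 - px[1]), 2.0)  # within the class-cell width
})

test_that("noise-free band values stay in the convex hull of class values", {
  s <- small_survey()
  base <- class_band_values(s$scene, default_camera_responses()[c("red", "green", "blue")])
  img <- s$views$images[[1]]
  # texture amplitude is clamped to [0.2, 1.8] of the class value
  expect_gte(min(img), 0.2 * min(base) - 1e-9)
  expect_lte(max(img), 1.8 * max(base) + 1e-9)
})

test_that("projection utilities agree with the longhand formulas", {
  set.seed(11)
  intr <- camera_intrinsics(focal = 436, width = 640, height = 480,
                            k1 = -0.08, k2 = 0.01)
  R <- rodrigues(rnorm(3, 0, 0.05)) %*% nadir_pose(c(0, 0, 0))$R
  pose <- camera_pose(R, c(5, -2, 18))
  X <- cbind(runif(20, 0, 10), runif(20, -5, 5), runif(20, 0, 2))
  px <- project_points(X, pose, intr)
  for (i in c(1, 7, 20))
    expect_equal(unname(px[i, ]),
                 oracle_project(X[i, ], pose$R, pose$centre, intr$focal,
                                intr$cx, intr$cy, intr$k1, intr$k2),
                 tolerance = 1e-10)
  # undistortion inverts the distortion model
  xn <- undistort_pixels(px, intr)
  redo <- shoremapper:::distort_normalised(xn, intr)
  expect_equal(redo[, 1] * intr$focal + intr$cx, px[, 1], tolerance = 1e-8)
})

test_that("rotation helpers round-trip", {
  set.seed(12)
  for (i in 1:20) {
    w <- rnorm(3) * runif(1, 0, 3)
    R <- rodrigues(w)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(rodrigues(rodrigues_inv(R)), R, tolerance = 1e-9)
  }
})
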