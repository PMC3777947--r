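test_that("scene generation is a pure function of its seed", {
  a <- generate_scene(size_m = c(20, 12), seed = 1)
  b <- generate_scene(size_m = c(20, 12), seed = 1)
  expect_identical(a$heightfield, b$heightfield)
  expect_identical(a$coverage, b$coverage)
  c <- generate_scene(size_m = c(20, 12), seed = 2)
  expect_false(identical(a$heightfield, c$heightfield))
})

test_that("cells below the water datum are labelled water, and only those", {
  sc <- generate_scene(size_m = c(20, 12), water_datum = 0.16, seed = 3)
  expect_identical(unname(sc$coverage == "water"),
                   unname(sc$heightfield < 0.16))
  expect_error(generate_scene(size_m = c(0, 10)), "degenerate")
})

test_that("single-class scenes have uniform flat reflectance", {
  sc <- generate_scene(size_m = c(20, 12), n_classes = 1, seed = 4)
  expect_setequal(unique(as.vector(sc$coverage)), c("uniform", "water"))
  expect_true(all(sc$class_spectra$uniform$reflectance == 0.5))
})

test_that("flight plans are deterministic zig-zags with footprint overlap", {
  sc <- generate_scene(seed = 1)
  intr <- camera_intrinsics(focal = 436, width = 640, height = 427)
  p1 <- plan_flight(sc, 15, 0.7, intr, seed = 5)
  p2 <- plan_flight(sc, 15, 0.7, intr, seed = 5)
  expect_equal(length(p1$poses), length(p2$poses))
  expect_identical(p1$poses[[3]]$centre, p2$poses[[3]]$centre)
  # footprint at 15 m with the default camera is about 22 x 15 m
  expect_equal(p1$footprint_m[1], 22, tolerance = 0.01)
  expect_equal(p1$footprint_m[2], 14.7, tolerance = 0.01)
  # consecutive footprints overlap by at least the set fraction (area)
  for (k in 1:3) {
    fr1 <- footprint_rect(p1$poses[[k]], intr)
    fr2 <- footprint_rect(p1$poses[[k + 1]], intr)
    ix <- max(min(fr1[2], fr2[2]) - max(fr1[1], fr2[1]), 0)
    iy <- max(min(fr1[4], fr2[4]) - max(fr1[3], fr2[3]), 0)
    ov <- ix * iy / ((fr1[2] - fr1[1]) * (fr1[4] - fr1[3]))
    expect_gte(ov, 0.55)  # requested 0.7 minus jitter allowance
  }
  expect_error(plan_flight(sc, 15, overlap = 1), "overlap")
  expect_error(plan_flight(sc, -3), "altitude")
})

test_that("GCP triads drape as near-equilateral triangles on dry land", {
  sc <- generate_scene(seed = 1)
  g <- place_gcps(sc, n_triads = 3, edge_m = 2, gps_noise_sd_m = 0, seed = 6)
  expect_equal(nrow(g$gcps), 9)   # three triads of three panels
  expect_equal(g$gcps$triad_id, rep(1:3, each = 3))
  for (t in 1:3) {
    P <- as.matrix(g$truth[g$truth$triad_id == t, c("x", "y", "z")])
    d3 <- c(dist(P))
    expect_true(all(abs(d3 - 2) < 1e-9))   # the tape fixes 3D separation
    zz <- g$truth$z[g$truth$triad_id == t]
    expect_true(all(zz > sc$water_datum))
    # panels rest on the terrain up to the draping tolerance
    expect_lt(max(abs(zz - scene_elevation(sc, P[, 1], P[, 2]))), 0.3)
  }
  # zero GPS noise: geodetic coordinates invert exactly to the true ENU
  enu <- geodetic_to_enu(g$gcps[, c("lat", "lon", "alt")],
                         sc$geodetic_origin)
  expect_equal(unname(enu), unname(as.matrix(g$truth[, c("x", "y", "z")])),
               tolerance = 1e-9)
  expect_error(place_gcps(sc, 0), "positive")
})

test_that("waterline points sit on the datum contour of the heightfield", {
  sc <- generate_scene(seed = 1)
  wl <- extract_waterline(sc)
  expect_gt(nrow(wl), 10)
  expect_true(all(wl$z == sc$water_datum))
  # resampling the contour onto the heightfield: residual bounded by the
  # local cell-size slope bound
  zh <- scene_elevation(sc, wl$x, wl$y)
  expect_lt(stats::median(abs(zh - sc$water_datum)), 0.05)
  dry <- generate_scene(size_m = c(10, 8), seed = 2)
  dry$heightfield[] <- 5
  expect_error(extract_waterline(dry), "dry")
})

test_that("a monotone ramp scene yields a single connected waterline", {
  sc <- generate_scene(size_m = c(10, 8), seed = 3)
  sc$heightfield <- matrix(rep(seq(-0.5, 1.5, length.out = nrow(sc$heightfield)),
                               ncol(sc$heightfield)),
                           nrow(sc$heightfield))
  wl <- extract_waterline(sc)
  # all points share (nearly) one northing: a single straight contour
  expect_lt(diff(range(wl$y)), 0.2)
})

test_that("the tangent-plane geodetic mapping round-trips", {
  origin <- c(lat = -35.0857, lon = 150.6933, alt = 0)
  set.seed(8)
  enu <- cbind(runif(50, -500, 500), runif(50, -500, 500), runif(50, -10, 10))
  back <- geodetic_to_enu(enu_to_geodetic(enu, origin), origin)
  expect_equal(unname(back), unname(enu), tolerance = 1e-9)
})
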