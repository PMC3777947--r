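test_that("a unit square with centre point triangulates into 4 faces", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
               c(0.5, 0.5, 0.3))
  mesh <- triangulate_surface(pts)
  expect_equal(nrow(mesh$faces), 4)
  expect_equal(nrow(mesh$vertices), 5)
  # duplicate plan positions collapse to one vertex
  mesh2 <- triangulate_surface(rbind(pts, c(0, 0, 9)))
  expect_equal(nrow(mesh2$vertices), 5)
  expect_error(triangulate_surface(cbind(1:5, 2 * (1:5), 0)), "collinear")
})

test_that("face normals are unit length and upward", {
  set.seed(61)
  pts <- cbind(runif(200, 0, 10), runif(200, 0, 10), runif(200, 0, 2))
  mesh <- triangulate_surface(pts)
  n <- mesh$normals
  expect_equal(sqrt(rowSums(n^2)), rep(1, nrow(n)), tolerance = 1e-9)
  expect_true(all(n[, 3] > 0))   # n_D < 0 in north-east-down terms
})

test_that("slope and aspect follow the normal-vector formulas exactly", {
  # horizontal face: slope 0, undefined aspect
  mesh <- triangulate_surface(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)))
  sa <- face_slope_aspect(mesh)
  expect_equal(sa$slope_deg, 0, tolerance = 1e-9)
  expect_true(is.na(sa$aspect_deg))
  # plane dipping 45 degrees toward east: slope 45, aspect 90
  mesh <- triangulate_surface(rbind(c(0, 0, 0), c(1, 0, -1), c(0, 1, 0),
                                    c(1, 1, -1)))
  sa <- face_slope_aspect(mesh)
  expect_equal(sa$slope_deg, rep(45, 2), tolerance = 1e-9)
  expect_equal(sa$aspect_deg, rep(90, 2), tolerance = 1e-9)
  # random analytic planes recovered to 1e-6 degrees
  set.seed(62)
  for (i in 1:20) {
    a <- runif(1, -1, 1); b <- runif(1, -1, 1)   # z = a x + b y
    pts <- cbind(runif(30, 0, 5), runif(30, 0, 5))
    pts <- cbind(pts, a * pts[, 1] + b * pts[, 2])
    mesh <- triangulate_surface(pts)
    sa <- face_slope_aspect(mesh)
    slope_true <- atan(sqrt(a^2 + b^2)) * 180 / pi
    aspect_true <- (atan2(-a, -b) * 180 / pi + 360) %% 360
    expect_lt(max(abs(sa$slope_deg - slope_true)), 1e-6)
    if (slope_true > 1e-3)
      expect_lt(max(abs(((sa$aspect_deg - aspect_true + 180) %% 360) - 180)),
                1e-6)
  }
})

test_that("aspect is equivariant under a 90-degree horizontal rotation", {
  set.seed(63)
  pts <- cbind(runif(100, 0, 8), runif(100, 0, 8), runif(100, 0, 3))
  mesh <- triangulate_surface(pts)
  sa <- face_slope_aspect(mesh)
  # rotate the mesh 90 degrees clockwise about the vertical axis:
  # (e, n) -> (n, -e); aspects gain 90 degrees (mod 360)
  rot <- cbind(pts[, 2], -pts[, 1], pts[, 3])
  mesh_r <- mesh
  mesh_r$vertices <- cbind(mesh$vertices[, 2], -mesh$vertices[, 1],
                           mesh$vertices[, 3])
  mesh_r <- shoremapper:::compute_face_normals(mesh_r)
  sa_r <- face_slope_aspect(mesh_r)
  expect_equal(sa_r$slope_deg, sa$slope_deg, tolerance = 1e-9)
  ok <- !is.na(sa$aspect_deg)
  expect_equal(sa_r$aspect_deg[ok] %% 360,
               (sa$aspect_deg[ok] + 90) %% 360, tolerance = 1e-9)
})

test_that("slope is invariant under translation and horizontal rotation", {
  set.seed(64)
  pts <- cbind(runif(80, 0, 6), runif(80, 0, 6), runif(80, 0, 2))
  mesh <- triangulate_surface(pts)
  sa <- face_slope_aspect(mesh)
  mesh_t <- mesh
  mesh_t$vertices <- mesh$vertices +
    matrix(c(100, -50, 20), nrow(mesh$vertices), 3, byrow = TRUE)
  mesh_t <- shoremapper:::compute_face_normals(mesh_t)
  expect_equal(face_slope_aspect(mesh_t)$slope_deg, sa$slope_deg,
               tolerance = 1e-9)
})

test_that("rasterisation interpolates elevation and carries face values", {
  # single horizontal face at z = 2
  mesh <- triangulate_surface(rbind(c(0, 0, 2), c(4, 0, 2), c(0, 4, 2),
                                    c(4, 4, 2)))
  rr <- rasterize_terrain(mesh, 0.5)
  v <- rr$elevation$values
  expect_true(all(v[v != -9999] == 2))
  expect_error(rasterize_terrain(
    structure(list(faces = matrix(0, 0, 3)), class = "terrain_mesh"), 0.5),
    "empty")
  # planar ramp: constant slope within half a degree away from edges
  a <- 0.3
  set.seed(65)
  pts <- cbind(runif(300, 0, 10), runif(300, 0, 10))
  pts <- cbind(pts, a * pts[, 1])
  mesh <- triangulate_surface(pts)
  rr <- rasterize_terrain(mesh, 0.2)
  sl <- rr$slope$values
  inner <- sl[10:40, 10:40]
  inner <- inner[inner != -9999]
  expect_lt(max(abs(inner - atan(a) * 180 / pi)), 0.5)
})

test_that("terrain recovery from sampled heightfield points is faithful", {
  scene <- generate_scene(size_m = c(20, 14), seed = 66)
  gsd <- 15 / 436
  set.seed(67)
  n <- 12000
  xs <- runif(n, 0, 20); ys <- runif(n, 0, 14)
  pts <- cbind(xs, ys, scene_elevation(scene, xs, ys))
  mesh <- triangulate_surface(pts, grid_m = 2 * gsd)
  rr <- rasterize_terrain(mesh, gsd)
  ev <- rr$elevation$values
  sel <- ev != -9999
  gx <- matrix(rep(rr$elevation$origin[1] +
                     (seq_len(ncol(ev)) - 1) * gsd, each = nrow(ev)), nrow(ev))
  gy <- matrix(rep(rr$elevation$origin[2] +
                     (seq_len(nrow(ev)) - 1) * gsd, ncol(ev)), nrow(ev))
  rmse <- sqrt(mean((ev[sel] - scene_elevation(scene, gx[sel], gy[sel]))^2))
  expect_lt(rmse, 2 * gsd)
})

test_that("long-edge faces bridging data gaps are removed", {
  set.seed(68)
  left <- cbind(runif(100, 0, 3), runif(100, 0, 3), 0)
  right <- cbind(runif(100, 9, 12), runif(100, 0, 3), 0)
  mesh <- triangulate_surface(rbind(left, right), max_edge_factor = 5)
  cent <- (mesh$vertices[mesh$faces[, 1], 1] +
             mesh$vertices[mesh$faces[, 2], 1] +
             mesh$vertices[mesh$faces[, 3], 1]) / 3
  expect_true(all(cent < 4 | cent > 8))  # nothing spans the gap
})

test_that("rasters write with world files and sample back", {
  mesh <- triangulate_surface(rbind(c(0, 0, 1), c(3, 0, 2), c(0, 3, 1),
                                    c(3, 3, 2)))
  rr <- rasterize_terrain(mesh, 0.5)
  expect_equal(raster_sample(rr$elevation, 1.5, 1.5),
               1.5, tolerance = 0.2)
  p <- tempfile(fileext = ".tif")
  write_raster(rr$elevation, p)
  expect_true(file.exists(p))
  expect_true(file.exists(sub(".tif", ".tfw", p, fixed = TRUE)))
  unlink(c(p, sub(".tif", ".tfw", p, fixed = TRUE),
           sub(".tif", ".json", p, fixed = TRUE)))
})
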