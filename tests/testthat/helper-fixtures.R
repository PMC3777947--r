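# Shared fixtures, built once per test session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small textured colour survey: 8 views at 640 x 480 over a 45 x 25 m shore
small_survey <- function() fixture("small_survey", function() {
  scene <- generate_scene(seed = 1)
  intr <- camera_intrinsics(focal = 436, width = 640, height = 480,
                            k1 = -0.08, k2 = 0.01)
  plan <- plan_flight(scene, 15, 0.7, intr, n_rows = 2, seed = 2)
  views <- render_views(scene, plan, intr, band = "colour", seed = 5)
  feats <- lapply(seq_along(views$images), function(i)
    extract_features(views$images[[i]], i))
  list(scene = scene, intr = intr, plan = plan, views = views, feats = feats)
})

# matched + reconstructed version of the small survey
small_model <- function() fixture("small_model", function() {
  s <- small_survey()
  matches <- match_all_pairs(s$feats, seed = 3)
  tg <- build_tracks(matches, s$feats,
                     bands = rep("colour", length(s$feats)))
  intr_init <- camera_intrinsics(focal = 436 * 1.05, width = 640,
                                 height = 480)
  model <- run_incremental_sfm(tg, list(intr_init),
                               rep(1L, length(s$feats)),
                               length(s$feats), seed = 4)
  c(s, list(matches = matches, tracks = tg, model = model))
})

# the full desk-scale demonstration survey (acceptance conditions)
full_demo <- function() fixture("full_demo", function() {
  demo_synthetic(seed = 42, scale = 1)
})

# paired reduced-scale runs (same seed) used by the determinism checks
demo_det_runs <- function() fixture("demo_det_runs", function() {
  list(a = demo_synthetic(seed = 7, scale = 0.35,
                          out_dir = file.path(tempdir(), "det_a")),
       b = demo_synthetic(seed = 7, scale = 0.35,
                          out_dir = file.path(tempdir(), "det_b")))
})

# a flat textured two-view fixture with known ground truth, for
# densification and epipolar tests
flat_two_view <- function() fixture("flat_two_view", function() {
  scene <- generate_scene(size_m = c(30, 22), n_classes = 1, relief_m = 0,
                          n_pools = 0, seed = 7)
  scene$heightfield[] <- 0.5   # exact plane above the water datum
  scene$coverage[] <- "uniform"
  intr <- camera_intrinsics(focal = 436, width = 640, height = 480)
  poses <- list(nadir_pose(c(12, 11, 15.5)), nadir_pose(c(15, 11, 15.5)))
  plan <- structure(list(poses = poses, altitude_m = 15,
                         footprint_m = c(640, 480) / 436 * 15,
                         overlap = 0.8, intr = intr),
                    class = "flight_plan")
  views <- render_views(scene, plan, intr, band = "colour", seed = 9)
  list(scene = scene, intr = intr, poses = poses, views = views)
})

# small mesh + true-pose model over the flat two-view fixture, extended to
# six cameras so best-4 selection is non-trivial
texture_fixture <- function() fixture("texture_fixture", function() {
  f <- flat_two_view()
  poses <- list(
    nadir_pose(c(10, 11, 15.0)), nadir_pose(c(12, 11, 15.3)),
    nadir_pose(c(14, 11, 15.6)), nadir_pose(c(16, 11, 15.9)),
    nadir_pose(c(12, 13, 16.2)), nadir_pose(c(14, 9, 16.5)))
  plan <- structure(list(poses = poses, intr = f$intr),
                    class = "flight_plan")
  views <- render_views(f$scene, plan, f$intr, band = "colour", seed = 9)
  model <- shoremapper:::new_model(list(), list(f$intr), rep(1L, 6), 6)
  model$poses <- poses
  set.seed(75)
  pts <- cbind(runif(900, 8, 19), runif(900, 7, 15))
  pts <- cbind(pts, 0.5)
  mesh <- triangulate_surface(pts, grid_m = 0.4)
  list(f = f, model = model, mesh = mesh, views = views, poses = poses)
})

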