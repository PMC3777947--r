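# file-driven pipeline: a tiny survey written to disk, run in stages with
# caching, annotation hand-off and invalidation on artefact corruption
test_that("run_pipeline executes, caches, resumes and invalidates", {
  root <- file.path(tempdir(), "filerun")
  unlink(root, recursive = TRUE)
  cdir <- file.path(root, "colour"); ndir <- file.path(root, "nir")
  out <- file.path(root, "out")
  dir.create(cdir, recursive = TRUE); dir.create(ndir, recursive = TRUE)

  scene <- generate_scene(size_m = c(26, 22), seed = 3)
  intr <- camera_intrinsics(436, 640, 480, k1 = -0.08, k2 = 0.01)
  plan_c <- plan_flight(scene, 15, 0.8, intr, n_rows = 2, n_views = 6,
                        seed = 4)
  plan_n <- plan_flight(scene, 15, 0.8, intr, n_rows = 2, n_views = 4,
                        seed = 5)
  vs_c <- render_views(scene, plan_c, intr, band = "colour",
                       tex_seed = 99, seed = 6)
  vs_n <- render_views(scene, plan_n, intr, band = "nir", exposure = 2.2,
                       tex_seed = 99, seed = 7)
  for (i in seq_along(vs_c$images))
    write_image_tiff(vs_c$images[[i]],
                     file.path(cdir, sprintf("c%02d.tif", i)), scale = 256)
  for (i in seq_along(vs_n$images))
    write_image_tiff(vs_n$images[[i]],
                     file.path(ndir, sprintf("n%02d.tif", i)), scale = 256)
  gc <- place_gcps(scene, 2, 2, gps_noise_sd_m = 0.5, seed = 8)
  write_gcp_csv(gc$gcps, file.path(root, "gcps.csv"))

  cfg <- pipeline_config(cdir, ndir, file.path(root, "gcps.csv"),
                         annotation_csv = file.path(root, "ann.csv"),
                         waterline_csv = file.path(root, "waterline.csv"),
                         out_dir = out, seed = 11,
                         origin = scene$geodetic_origin)
  # YAML round trip
  write_pipeline_config(cfg, file.path(root, "survey.yaml"))
  cfg2 <- read_pipeline_config(file.path(root, "survey.yaml"))
  expect_equal(cfg2$seed, 11)
  expect_equal(cfg2$params$zncc_min, cfg$params$zncc_min)

  # first run: reconstruction only, waiting for annotations
  m1 <- run_pipeline(cfg, verbose = FALSE)
  expect_equal(m1$stages$match$status, "computed")
  expect_equal(m1$stages$sfm$status, "computed")
  expect_equal(m1$stages$georef$status, "pending annotations")
  expect_true(file.exists(file.path(out, "model.json")))
  expect_true(file.exists(file.path(out, "dense.ply")))

  # annotate from ground truth (manual pointcloud identification stand-in)
  model <- readRDS(file.path(out, "cache", "densify.rds"))
  true_poses <- c(plan_c$poses, plan_n$poses)
  ann <- locate_in_model(model, true_poses, list(intr, intr),
                         as.matrix(gc$truth[, c("x", "y", "z")]))
  expect_false(anyNA(ann))
  write.csv(data.frame(id = gc$gcps$id, x = ann[, 1], y = ann[, 2],
                       z = ann[, 3]),
            file.path(root, "ann.csv"), row.names = FALSE)
  wl_true <- extract_waterline(scene, max_points = 120)
  wl_rec <- locate_in_model(model, true_poses, list(intr, intr),
                            as.matrix(wl_true))
  wl_rec <- wl_rec[!is.na(wl_rec[, 1]), , drop = FALSE]
  write.csv(data.frame(x = wl_rec[, 1], y = wl_rec[, 2], z = wl_rec[, 3]),
            file.path(root, "waterline.csv"), row.names = FALSE)

  # second run: reconstruction cached, geo-referencing + products computed
  m2 <- run_pipeline(cfg, verbose = FALSE)
  expect_equal(m2$stages$match$status, "cached")
  expect_equal(m2$stages$sfm$status, "cached")
  expect_equal(m2$stages$densify$status, "cached")
  expect_equal(m2$stages$georef$status, "computed")
  expect_equal(m2$stages$ndvi$status, "computed")
  expect_true(file.exists(file.path(out, "ndvi.tif")))
  expect_true(file.exists(file.path(out, "elevation.tif")))
  expect_lt(m2$georef_report$local_residual_m, 0.05)

  # third run: everything cached
  m3 <- run_pipeline(cfg, verbose = FALSE)
  expect_true(all(vapply(m3$stages, `[[`, "", "status") == "cached"))

  # corrupting a cached stage artefact re-runs it and all downstream
  writeLines("corrupt", file.path(out, "cache", "terrain.rds"))
  m4 <- run_pipeline(cfg, verbose = FALSE)
  expect_equal(m4$stages$georef$status, "cached")
  expect_equal(m4$stages$terrain$status, "computed")
  expect_equal(m4$stages$mosaic$status, "computed")
  expect_equal(m4$stages$ndvi$status, "computed")
  unlink(root, recursive = TRUE)
})
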