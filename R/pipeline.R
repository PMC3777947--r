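#' Default pipeline parameters
#'
#' All tunable stage parameters with their defaults, echoed into run
#' manifests for reproducibility.
#'
#' @return Named list of parameters.
#' @export
default_parameters <- function() {
  list(
    ratio = 0.8, epi_threshold_px = 2, min_inliers = 16,
    max_features = 1500, feature_rel_thresh = 1e-6,
    min_tri_angle_deg = 2, huber_px = 2, prune_px = 4, ba_every = 4,
    densify_cell_px = 5, densify_half = 3, zncc_min = 0.85,
    mesh_grid_factor = 2, outlier_cell_m = 0.25, outlier_max_dev_m = 0.2,
    mosaic_cell_factor = 1, datum_height_m = 0.16,
    focal_prior_error = 1.03, altitude_m = 15,
    n_colour = 24, n_nir = 20, width = 640, height = 480,
    focal_px = 436, k1 = -0.08, k2 = 0.01,
    exposure_colour = 1, exposure_nir = 2.2,
    gps_noise_sd_m = 1.2, n_triads = 3, edge_m = 2,
    noise_sd = 0, n_patches = 167, patch_px = 15,
    scene_length_m = 60, scene_width_m = 25
  )
}

#' One-command synthetic demonstration survey
#'
#' Generates a synthetic shore, renders colour and near-infrared kite
#' flights over it, runs the full pipeline (feature matching, incremental
#' structure-from-motion, self-calibrating bundle adjustment,
#' densification, GCP geo-registration with waterline datum correction,
#' terrain surfacing, texturing, NDVI), compares every product against
#' the known ground truth and returns a pass/fail accuracy report.
#'
#' `scale` scales the survey (scene length and number of views), not the
#' image resolution, so the reconstruction operates in the same imaging
#' regime at any scale.
#'
#' @param seed Integer seed controlling every random element.
#' @param scale Survey scale factor (1 = full desk-scale survey of
#'   roughly 24 colour + 20 NIR views over a 45 x 25 m shore).
#' @param out_dir Optional directory for artefacts (model JSON, PLY
#'   clouds, rasters, report and manifest).
#' @param params Parameter overrides (see [default_parameters()]).
#' @param verbose Print stage progress.
#' @return List with `report` (data frame of accuracy checks), `model`,
#'   `mosaic`, `ndvi`, `georef`, `match_stats`, `patch_stats`, `gsd_m`,
#'   `manifest`.
#' @export
demo_synthetic <- function(seed = 42, scale = 1, out_dir = NULL,
                           params = list(), verbose = FALSE) {
  p <- utils::modifyList(default_parameters(), params)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  ## --- synthetic survey ---------------------------------------------------
  size_m <- c(p$scene_length_m * max(scale, 0.25), p$scene_width_m)
  scene <- generate_scene(size_m = size_m, water_datum = p$datum_height_m,
                          seed = seed)
  intr_true <- camera_intrinsics(p$focal_px, p$width, p$height,
                                 k1 = p$k1, k2 = p$k2)
  n_col <- max(8, round(p$n_colour * scale))
  n_nir <- max(6, round(p$n_nir * scale))
  plan_c <- plan_flight(scene, p$altitude_m, overlap = 0.85, intr_true,
                        n_rows = 2, n_views = n_col, seed = seed + 1)
  plan_n <- plan_flight(scene, p$altitude_m, overlap = 0.85, intr_true,
                        n_rows = 2, n_views = n_nir, seed = seed + 2)
  responses <- default_camera_responses()
  say("rendering %d colour + %d NIR views",
      length(plan_c$poses), length(plan_n$poses))
  vs_c <- render_views(scene, plan_c, intr_true, responses, "colour",
                       exposure = p$exposure_colour, noise_sd = p$noise_sd,
                       tex_seed = seed + 90, seed = seed + 3)
  vs_n <- render_views(scene, plan_n, intr_true, responses, "nir",
                       exposure = p$exposure_nir, noise_sd = p$noise_sd,
                       tex_seed = seed + 90, seed = seed + 4)
  images <- c(vs_c$images, vs_n$images)
  true_poses <- c(plan_c$poses, plan_n$poses)
  n_images <- length(images)
  bands <- c(rep("colour", length(vs_c$images)), rep("nir", length(vs_n$images)))
  body <- ifelse(bands == "colour", 1L, 2L)

  ## --- features / matching / tracks --------------------------------------
  say("extracting features")
  feats <- lapply(seq_len(n_images), function(i)
    extract_features(images[[i]], i, rel_thresh = p$feature_rel_thresh,
                     max_features = p$max_features))
  say("matching %d image pairs", n_images * (n_images - 1) / 2)
  matches <- match_all_pairs(feats, ratio = p$ratio,
                             epi_threshold_px = p$epi_threshold_px,
                             seed = seed + 5, min_inliers = p$min_inliers)
  mstats <- match_statistics(matches, bands)
  tg <- build_tracks(matches, feats, bands)
  say("%d tracks (%d cross-band)", length(tg$tracks),
      sum(tg$band_coverage == "both", na.rm = TRUE))

  ## --- structure-from-motion + densification -----------------------------
  intr_init <- list(
    camera_intrinsics(p$focal_px * p$focal_prior_error, p$width, p$height),
    camera_intrinsics(p$focal_px * p$focal_prior_error, p$width, p$height))
  say("incremental SfM")
  model <- run_incremental_sfm(tg, intr_init, body, n_images,
                               seed = seed + 6, ba_every = p$ba_every,
                               min_tri_angle_deg = p$min_tri_angle_deg,
                               huber_px = p$huber_px, prune_px = p$prune_px,
                               verbose = verbose)
  say("registered %d/%d images, RMSE %.3f px",
      length(registered_ids(model)), n_images, model$rmse)
  say("densifying")
  model <- densify(model, images, cell_px = p$densify_cell_px,
                   half = p$densify_half, zncc_min = p$zncc_min,
                   bands = bands)
  say("%d dense points", nrow(model$dense))

  ## --- geo-registration ---------------------------------------------------
  gc <- place_gcps(scene, p$n_triads, p$edge_m, p$gps_noise_sd_m,
                   seed = seed + 7)
  ann <- locate_in_model(model, true_poses, list(intr_true, intr_true),
                         as.matrix(gc$truth[, c("x", "y", "z")]))
  # keep only triads whose three panels were all identified
  located <- !is.na(ann[, 1])
  ok_triads <- vapply(split(located, gc$gcps$triad_id), all, TRUE)
  keep <- gc$gcps$triad_id %in% names(ok_triads)[ok_triads]
  if (!any(keep))
    stop("no complete GCP triad could be located in the reconstruction")
  if (!all(keep))
    warning(sum(!keep), " GCP(s) in incomplete triads dropped")
  gc$gcps <- gc$gcps[keep, ]
  gc$truth <- gc$truth[keep, ]
  ann <- ann[keep, , drop = FALSE]
  gcps <- annotate_gcps(gc$gcps, ann)
  geo <- georegister(model, gcps, scene$geodetic_origin)
  model_geo <- geo$model
  wl_true <- extract_waterline(scene)
  wl_model <- locate_in_model(model, true_poses, list(intr_true, intr_true),
                              as.matrix(wl_true))
  wl_model <- wl_model[!is.na(wl_model[, 1]), , drop = FALSE]
  wl_geo <- apply_similarity(geo$transform, wl_model)
  datum <- adjust_vertical_datum(model_geo, wl_geo, p$datum_height_m)
  model_geo <- datum$model
  tf_prod <- compose_similarity(datum$transform, geo$transform)
  say("georegistered: global %.3f m, local %.4f m, datum shift %.3f m",
      geo$report$global_residual_m, geo$report$local_residual_m,
      datum$shift_m)

  ## Validation transform: geo-registration against the *true* GCP
  ## coordinates (as if surveyed error-free).  Handheld-GPS noise tilts
  ## and offsets the product frame by design; reconstruction-fidelity
  ## metrics and ground-truth lookups must not inherit that.
  geo_exact <- enu_to_geodetic(as.matrix(gc$truth[, c("x", "y", "z")]),
                               scene$geodetic_origin)
  gcps_true <- annotate_gcps(
    data.frame(id = gc$gcps$id, triad_id = gc$gcps$triad_id,
               lat = geo_exact[, 1], lon = geo_exact[, 2],
               alt = geo_exact[, 3], edge_m = p$edge_m), ann)
  geo_val <- georegister(NULL, gcps_true, scene$geodetic_origin)
  wl_val <- apply_similarity(geo_val$transform, wl_model)
  shift_val <- similarity_transform(1, diag(3),
                                    c(0, 0, p$datum_height_m - mean(wl_val[, 3])))
  tf_val <- compose_similarity(shift_val, geo_val$transform)
  # maps product-frame coordinates to true world coordinates
  map_to_truth <- compose_similarity(tf_val, invert_similarity(tf_prod))

  ## --- terrain + mosaics + NDVI -------------------------------------------
  reg <- registered_ids(model_geo)
  alt <- stats::median(vapply(reg, function(i)
    apply_similarity(tf_val, model$poses[[i]]$centre)[3], 0)) -
    mean(scene$heightfield)
  gsd <- alt / model_geo$intr[[1]]$focal
  say("ground sampling distance %.1f mm", gsd * 1000)
  mesh <- triangulate_surface(model_geo$dense,
                              grid_m = p$mesh_grid_factor * gsd,
                              outlier_filter = list(cell = p$outlier_cell_m,
                                                    max_dev = p$outlier_max_dev_m))
  assignments <- select_views(mesh, model_geo, bands)
  mosaic <- render_orthomosaic(mesh, model_geo, images, assignments,
                               cell_m = p$mosaic_cell_factor * gsd,
                               crs = as.list(scene$geodetic_origin))
  spectralon <- spectralon_values(responses,
                                  exposures = c(red = p$exposure_colour,
                                                green = p$exposure_colour,
                                                blue = p$exposure_colour,
                                                nir = p$exposure_nir))
  gains <- white_balance_gains(spectralon[c("red", "nir")])
  ndvi <- compute_ndvi(mosaic, gains)
  # prediction must include the survey exposure times the mosaic values carry
  gains_pred <- c(red = gains[["red"]] * p$exposure_colour,
                  nir = gains[["nir"]] * p$exposure_nir)
  predicted <- vapply(scene$classes, function(cl)
    predict_ndvi(scene$class_spectra[[cl]], responses$red, responses$nir,
                 gains_pred), 0)
  centres <- pure_patch_centres(scene, ndvi, p$patch_px, p$n_patches,
                                map_to_truth = map_to_truth,
                                elev = mosaic$terrain$elevation)
  pstats <- if (nrow(centres) > 0)
    patch_statistics(ndvi, centres, p$patch_px, predicted) else NULL

  ## --- accuracy report ----------------------------------------------------
  al <- align_to_truth(model, true_poses)
  dm <- apply_similarity(tf_val, model$dense)
  dz <- dm[, 3] - scene_elevation(scene, dm[, 1], dm[, 2])
  # 3D distance to the true surface: vertical residual foreshortened by slope
  gstep <- scene$cell_m
  gxp <- (scene_elevation(scene, dm[, 1] + gstep, dm[, 2]) -
            scene_elevation(scene, dm[, 1] - gstep, dm[, 2])) / (2 * gstep)
  gyp <- (scene_elevation(scene, dm[, 1], dm[, 2] + gstep) -
            scene_elevation(scene, dm[, 1], dm[, 2] - gstep)) / (2 * gstep)
  d3 <- abs(dz) / sqrt(1 + gxp^2 + gyp^2)
  mesh_val <- triangulate_surface(dm, grid_m = p$mesh_grid_factor * gsd,
                                  outlier_filter = list(cell = p$outlier_cell_m,
                                                        max_dev = p$outlier_max_dev_m))
  ev <- rasterize_terrain(mesh_val, p$mosaic_cell_factor * gsd)$elevation
  sel <- ev$values != ev$nodata
  xs <- ev$origin[1] + (seq_len(ncol(ev$values)) - 1) * ev$cell_m
  ys <- ev$origin[2] + (seq_len(nrow(ev$values)) - 1) * ev$cell_m
  gx <- matrix(rep(xs, each = nrow(ev$values)), nrow(ev$values))
  gy <- matrix(rep(ys, ncol(ev$values)), nrow(ev$values))
  elev_rmse <- sqrt(mean((ev$values[sel] -
                            scene_elevation(scene, gx[sel], gy[sel]))^2))
  # densification density: points per cell_px^2 patch of usable image area
  usable <- vapply(reg, function(i) {
    ii <- model_geo$intr[[model_geo$body[i]]]
    b <- p$densify_half + p$densify_cell_px
    (ii$width - 2 * b) * (ii$height - 2 * b)
  }, 0)
  density_ratio <- nrow(dm) / (sum(usable) / p$densify_cell_px^2)
  algae <- grep("algae", scene$classes, value = TRUE)
  meas <- if (!is.null(pstats) && !is.null(pstats$by_label))
    stats::setNames(pstats$by_label$mean, pstats$by_label$label) else c()
  ndvi_err <- if (length(meas) > 0)
    max(abs(meas - predicted[names(meas)])) else NA_real_

  checks <- list(
    list("views registered fraction",
         length(reg) / n_images, ">= 0.9",
         length(reg) / n_images >= 0.9),
    list("reprojection RMSE (px)", model$rmse, "< 1", model$rmse < 1),
    list("camera centre RMSE / flying height", al$rmse / alt, "< 0.01",
         al$rmse / alt < 0.01),
    list("focal length relative error",
         abs(model$intr[[1]]$focal - p$focal_px) / p$focal_px, "< 0.01",
         abs(model$intr[[1]]$focal - p$focal_px) / p$focal_px < 0.01),
    list("median dense 3D error / GSD", stats::median(d3) / gsd, "< 2",
         stats::median(d3) < 2 * gsd),
    list("elevation raster RMSE / GSD", elev_rmse / gsd, "< 2",
         elev_rmse < 2 * gsd),
    list("local (edge) residual (m)", geo$report$local_residual_m, "< 0.05",
         geo$report$local_residual_m < 0.05),
    list("global residual / GPS noise",
         geo$report$global_residual_m / p$gps_noise_sd_m, "< 3",
         geo$report$global_residual_m < 3 * p$gps_noise_sd_m),
    list("densification density ratio", density_ratio,
         "in [0.5, 2]", density_ratio >= 0.5 && density_ratio <= 2),
    list("max |measured - predicted| NDVI", ndvi_err, "< 0.05",
         is.finite(ndvi_err) && ndvi_err < 0.05),
    list("algae NDVI in live range",
         if (length(meas)) mean(meas[intersect(algae, names(meas))]) else NA,
         "in [0.3, 0.7]",
         all(meas[intersect(algae, names(meas))] >= 0.3 &
               meas[intersect(algae, names(meas))] <= 0.7)),
    list("water NDVI approaching -1",
         unname(meas["water"]), "< -0.7",
         !is.na(meas["water"]) && meas["water"] < -0.7)
  )
  report <- do.call(rbind, lapply(checks, function(ck)
    data.frame(check = ck[[1]], value = as.numeric(ck[[2]]),
               threshold = ck[[3]], pass = isTRUE(ck[[4]]))))
  say("demo complete in %.1f min: %d/%d checks pass",
      as.numeric(difftime(Sys.time(), t_start, units = "mins")),
      sum(report$pass), nrow(report))

  out <- list(report = report, model = model_geo, mosaic = mosaic,
              ndvi = ndvi, georef = geo$report,
              datum_shift_m = datum$shift_m,
              match_stats = mstats, patch_stats = pstats,
              predicted_ndvi = predicted, gains = gains, gsd_m = gsd,
              scene = scene, true_poses = true_poses,
              alignment = list(rmse = al$rmse, transform = al$transform),
              seed = seed, params = p)
  if (!is.null(out_dir)) out$manifest <- write_demo_artifacts(out, out_dir)
  out
}

# candidate patch centres fully inside one coverage class and mosaic;
# labels come from the true class map, so mosaic-frame coordinates are
# mapped back to true world coordinates first (the field protocol's
# manual identification knows what each patch is)
pure_patch_centres <- function(scene, ndvi, patch_px, n_patches,
                               map_to_truth = NULL, elev = NULL) {
  v <- ndvi$values
  hw <- (patch_px - 1) / 2
  step <- patch_px + 2
  cand <- expand.grid(cy = seq(hw + 1, nrow(v) - hw, by = step),
                      cx = seq(hw + 1, ncol(v) - hw, by = step))
  keep <- list()
  for (i in seq_len(nrow(cand))) {
    cy <- cand$cy[i]; cx <- cand$cx[i]
    block <- v[(cy - hw):(cy + hw), (cx - hw):(cx + hw)]
    if (any(block == ndvi$nodata)) next
    # world coords of patch corners and centre must share one class
    xs <- ndvi$origin[1] + (c(cx - hw, cx, cx + hw) - 1) * ndvi$cell_m
    ys <- ndvi$origin[2] + (c(cy - hw, cy, cy + hw) - 1) * ndvi$cell_m
    P <- cbind(rep(xs, each = 3), rep(ys, 3), 0)
    if (!is.null(map_to_truth)) {
      if (!is.null(elev)) {
        z <- raster_sample(elev, P[, 1], P[, 2])
        if (anyNA(z)) next
        P[, 3] <- z
      }
      P <- apply_similarity(map_to_truth, P)
    }
    cl <- scene_class(scene, P[, 1], P[, 2])
    if (length(unique(cl)) != 1) next
    keep[[length(keep) + 1]] <- data.frame(cx = cx, cy = cy, label = cl[1])
  }
  if (length(keep) == 0)
    return(data.frame(cx = integer(0), cy = integer(0), label = character(0)))
  out <- do.call(rbind, keep)
  # balance across classes up to n_patches total
  out <- do.call(rbind, lapply(split(out, out$label), function(g)
    utils::head(g, ceiling(n_patches / length(unique(out$label))))))
  rownames(out) <- NULL
  utils::head(out, n_patches)
}

write_demo_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }
  write_model_json(res$model, w(file.path(out_dir, "model.json")))
  write_ply_points(res$model$points[!is.na(res$model$points[, 1]), ],
                   w(file.path(out_dir, "sparse.ply")))
  write_ply_points(res$model$dense, w(file.path(out_dir, "dense.ply")))
  write_raster(res$mosaic$terrain$elevation,
               w(file.path(out_dir, "elevation.tif")))
  write_raster(res$mosaic$terrain$slope, w(file.path(out_dir, "slope.tif")))
  write_raster(res$mosaic$terrain$aspect, w(file.path(out_dir, "aspect.tif")))
  write_raster(res$ndvi, w(file.path(out_dir, "ndvi.tif")))
  for (b in c("red", "green", "blue", "nir"))
    if (!is.null(res$mosaic[[b]]))
      write_raster(res$mosaic[[b]], w(file.path(out_dir, paste0(b, ".tif"))))
  utils::write.csv(res$report, w(file.path(out_dir, "report.csv")),
                   row.names = FALSE)
  utils::write.csv(res$match_stats, w(file.path(out_dir, "match_stats.csv")),
                   row.names = FALSE)
  if (!is.null(res$patch_stats$by_label))
    utils::write.csv(res$patch_stats$by_label,
                     w(file.path(out_dir, "ndvi_validation.csv")),
                     row.names = FALSE)
  manifest <- list(
    seed = res$seed, parameters = res$params,
    gsd_m = res$gsd_m, georef = res$georef,
    artefacts = lapply(stats::setNames(paths, basename(paths)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  manifest
}
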