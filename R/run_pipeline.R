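#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration consumed by
#' [run_pipeline()]: input paths, stage parameters, seed, geodetic origin
#' and tidal datum height.  All stage parameters default to
#' [default_parameters()] and are echoed into the run manifest.
#'
#' @param colour_dir,nir_dir Directories of colour / near-infrared images
#'   (TIFF, alphabetical order).
#' @param gcp_csv GCP table CSV (`id, triad_id, lat, lon, alt, edge_m`).
#' @param annotation_csv GCP annotations in reconstruction coordinates
#'   (`id, x, y, z`); may be `NULL` until the reconstruction exists.
#' @param waterline_csv Waterline points in reconstruction coordinates
#'   (`x, y, z`); optional.
#' @param out_dir Output/cache directory.
#' @param seed Integer seed (mandatory).
#' @param origin Geodetic origin `c(lat, lon, alt)` of the ENU frame.
#' @param datum_height_m Tidal datum height of the water surface (m).
#' @param image_scale Value scaling used when the TIFFs were written.
#' @param params Stage parameter overrides.
#' @return A config list (class `"pipeline_config"`).
#' @export
pipeline_config <- function(colour_dir, nir_dir, gcp_csv,
                            annotation_csv = NULL, waterline_csv = NULL,
                            out_dir = "shoremapper_out", seed = 1,
                            origin = c(lat = -35.0857, lon = 150.6933, alt = 0),
                            datum_height_m = 0.16, image_scale = 256,
                            params = list()) {
  stopifnot(!missing(seed))
  structure(list(colour_dir = colour_dir, nir_dir = nir_dir,
                 gcp_csv = gcp_csv, annotation_csv = annotation_csv,
                 waterline_csv = waterline_csv, out_dir = out_dir,
                 seed = as.integer(seed), origin = origin,
                 datum_height_m = datum_height_m,
                 image_scale = image_scale,
                 params = utils::modifyList(default_parameters(), params)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    y[setdiff(names(y), c("params", "origin"))],
    list(origin = unlist(y$origin), params = y$params %||% list())))
}

#' @rdname pipeline_config
#' @param config A config to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

md5_files <- function(paths) unname(tools::md5sum(paths))

#' Run the full mapping pipeline from files
#'
#' Executes match, sfm, densify, georef, terrain, mosaic and ndvi in
#' order, caching each stage on disk.  A stage is reused when its
#' parameters, its input files and every upstream stage are unchanged and
#' its cached artefacts are intact; any change (or a corrupted artefact)
#' re-runs that stage and everything downstream.  A structured manifest
#' (JSON) with per-stage status, input hashes, artefact checksums and the
#' full parameter echo is written to the output directory.
#'
#' GCP/waterline annotations live in reconstruction coordinates, so they
#' can only be produced once the reconstruction exists; when
#' `annotation_csv` is not yet available the run stops after densify with
#' an actionable message, and a later run (annotations in hand) reuses
#' the cached reconstruction.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return The run manifest (list), invisibly; artefacts and
#'   `manifest.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  out <- config$out_dir
  cache <- file.path(out, "cache")
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  manifest <- list(seed = config$seed, parameters = p, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))

  stale <- FALSE  # once a stage recomputes, everything downstream does
  stage <- function(name, inputs, artefacts, fn) {
    key <- md5_of(list(inputs, p, config$seed))
    prev <- old_manifest$stages[[name]]
    paths <- file.path(cache, paste0(name, ".rds"))
    ok_cache <- !stale && !is.null(prev) && identical(prev$key, key) &&
      file.exists(paths) &&
      identical(unname(unlist(prev$artefact_md5)), md5_files(paths))
    t0 <- Sys.time()
    if (ok_cache) {
      res <- readRDS(paths)
      status <- "cached"
    } else {
      stale <<- TRUE
      res <- fn()
      saveRDS(res, paths, version = 3)
      status <- "computed"
    }
    manifest$stages[[name]] <<- list(
      status = status, key = key,
      artefact_md5 = as.list(md5_files(paths)),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    say("stage %-8s %s (%.1fs)", name, status,
        manifest$stages[[name]]$seconds)
    res
  }
  finish <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = 12, pretty = TRUE)
    invisible(manifest)
  }

  img_files_c <- sort(list.files(config$colour_dir, "\\.tiff?$",
                                 full.names = TRUE))
  img_files_n <- sort(list.files(config$nir_dir, "\\.tiff?$",
                                 full.names = TRUE))
  if (length(img_files_c) + length(img_files_n) < 2)
    stop("no images found in the configured directories")
  bands <- c(rep("colour", length(img_files_c)),
             rep("nir", length(img_files_n)))
  body <- ifelse(bands == "colour", 1L, 2L)
  n_images <- length(bands)
  images <- NULL
  load_images <- function() {
    if (is.null(images))
      images <<- lapply(c(img_files_c, img_files_n), read_image_tiff,
                        scale = config$image_scale)
    images
  }

  matched <- stage("match", md5_files(c(img_files_c, img_files_n)),
                   "match", function() {
    imgs <- load_images()
    feats <- lapply(seq_len(n_images), function(i)
      extract_features(imgs[[i]], i, rel_thresh = p$feature_rel_thresh,
                       max_features = p$max_features))
    matches <- match_all_pairs(feats, ratio = p$ratio,
                               epi_threshold_px = p$epi_threshold_px,
                               seed = config$seed + 5,
                               min_inliers = p$min_inliers)
    list(tracks = build_tracks(matches, feats, bands),
         stats = match_statistics(matches, bands))
  })

  model <- stage("sfm", manifest$stages$match$key, "sfm", function() {
    intr_init <- list(
      camera_intrinsics(p$focal_px * p$focal_prior_error, p$width, p$height),
      camera_intrinsics(p$focal_px * p$focal_prior_error, p$width, p$height))
    run_incremental_sfm(matched$tracks, intr_init, body, n_images,
                        seed = config$seed + 6, ba_every = p$ba_every,
                        min_tri_angle_deg = p$min_tri_angle_deg,
                        huber_px = p$huber_px, prune_px = p$prune_px)
  })
  write_model_json(model, file.path(out, "model.json"))

  model <- stage("densify", manifest$stages$sfm$key, "densify", function() {
    densify(model, load_images(), cell_px = p$densify_cell_px,
            half = p$densify_half, zncc_min = p$zncc_min, bands = bands)
  })
  write_ply_points(model$dense, file.path(out, "dense.ply"))

  if (is.null(config$annotation_csv) || !file.exists(config$annotation_csv)) {
    say(paste("reconstruction complete; annotate the GCPs (and waterline)",
              "in reconstruction coordinates, set annotation_csv, and",
              "re-run to geo-reference"))
    manifest$stages$georef <- list(status = "pending annotations")
    return(finish())
  }

  geo <- stage("georef",
               list(manifest$stages$densify$key,
                    md5_files(c(config$gcp_csv, config$annotation_csv,
                                config$waterline_csv))),
               "georef", function() {
    gcps <- read_gcp_csv(config$gcp_csv)
    ann <- read_gcp_csv(config$annotation_csv)
    ann <- ann[match(gcps$id, ann$id), ]
    gcps <- annotate_gcps(gcps, as.matrix(ann[, c("x", "y", "z")]))
    g <- georegister(model, gcps, config$origin)
    if (!is.null(config$waterline_csv) && file.exists(config$waterline_csv)) {
      wl <- as.matrix(utils::read.csv(config$waterline_csv))
      wl_geo <- apply_similarity(g$transform, wl[, 1:3, drop = FALSE])
      d <- adjust_vertical_datum(g$model, wl_geo, config$datum_height_m)
      g$model <- d$model
      g$report$datum_shift_m <- d$shift_m
      g$transform <- compose_similarity(d$transform, g$transform)
    }
    g
  })
  manifest$georef_report <- geo$report
  model_geo <- geo$model

  gsd <- {
    reg <- registered_ids(model_geo)
    zc <- stats::median(vapply(reg, function(i)
      model_geo$poses[[i]]$centre[3], 0))
    (zc - stats::median(model_geo$dense[, 3])) / model_geo$intr[[1]]$focal
  }
  manifest$gsd_m <- gsd

  terra <- stage("terrain", manifest$stages$georef$key, "terrain", function() {
    mesh <- triangulate_surface(model_geo$dense,
                                grid_m = p$mesh_grid_factor * gsd,
                                outlier_filter = list(
                                  cell = p$outlier_cell_m,
                                  max_dev = p$outlier_max_dev_m))
    list(mesh = mesh,
         rasters = rasterize_terrain(mesh, p$mosaic_cell_factor * gsd,
                                     crs = as.list(config$origin)))
  })
  write_ply_mesh(terra$mesh, file.path(out, "terrain.ply"))
  for (b in c("elevation", "slope", "aspect"))
    write_raster(terra$rasters[[b]], file.path(out, paste0(b, ".tif")))

  mosaic <- stage("mosaic", manifest$stages$terrain$key, "mosaic", function() {
    sel <- select_views(terra$mesh, model_geo, bands)
    render_orthomosaic(terra$mesh, model_geo, load_images(), sel,
                       cell_m = p$mosaic_cell_factor * gsd,
                       crs = as.list(config$origin))
  })
  for (b in c("red", "green", "blue", "nir"))
    if (!is.null(mosaic[[b]]))
      write_raster(mosaic[[b]], file.path(out, paste0(b, ".tif")))

  ndvi <- stage("ndvi", manifest$stages$mosaic$key, "ndvi", function() {
    spectralon <- spectralon_values(default_camera_responses(),
                                    exposures = c(red = p$exposure_colour,
                                                  green = p$exposure_colour,
                                                  blue = p$exposure_colour,
                                                  nir = p$exposure_nir))
    compute_ndvi(mosaic, white_balance_gains(spectralon[c("red", "nir")]))
  })
  write_raster(ndvi, file.path(out, "ndvi.tif"))
  finish()
}
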