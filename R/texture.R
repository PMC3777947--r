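#' Assign the best views to each terrain face
#'
#' For every mesh face and each camera band, finds the images that
#' actually see the face (projection inside bounds, face front-facing,
#' unoccluded against a per-image z-buffer) and keeps the four with the
#' smallest face-centre-to-camera distance (highest ground resolution).
#' Ties on distance break deterministically by image id.  Blend weights
#' decrease with rank as (4,3,2,1) and are normalised over the views
#' actually assigned.
#'
#' @param mesh A [triangulate_surface()] mesh in the model frame.
#' @param model Registered `"recon_model"` in the same frame.
#' @param bands Band label per image id (`"colour"` / `"nir"`).
#' @param max_views Views kept per face per band (4).
#' @param downscale Z-buffer resolution divisor.
#' @param occlusion_tol_m Depth slack for the occlusion test (metres, in
#'   model units).
#' @return List per band: `assign` (nface x 4 image ids, 0 = none),
#'   `weights` (nface x 4), `n_seen` (views seeing each face).
#' @export
select_views <- function(mesh, model, bands, max_views = 4, downscale = 2,
                         occlusion_tol_m = 0.05) {
  reg <- registered_ids(model)
  centres <- face_centres(mesh)
  normals <- mesh$normals
  nf <- nrow(centres)
  out <- list()
  for (band in unique(bands[reg])) {
    cams <- reg[bands[reg] == band]
    dist <- matrix(Inf, nf, length(cams))
    for (k in seq_along(cams)) {
      i <- cams[k]
      pose <- model$poses[[i]]
      intr <- model$intr[[model$body[i]]]
      px <- project_points(centres, pose, intr)
      depth <- attr(px, "depth")
      ok <- !is.na(px[, 1]) &
        px[, 1] >= 1 & px[, 1] <= intr$width - 2 &
        px[, 2] >= 1 & px[, 2] <= intr$height - 2
      # front-facing: camera on the upper side of the face
      view <- matrix(pose$centre, nf, 3, byrow = TRUE) - centres
      ok <- ok & rowSums(view * normals) > 0
      # occlusion via z-buffer
      zb <- depth_render_cpp(mesh$vertices, mesh$faces, pose$R, pose$centre,
                             c(intr$focal, intr$cx, intr$cy, intr$k1, intr$k2),
                             intr$width, intr$height, as.integer(downscale))
      iu <- pmin(pmax(round(px[, 1] / downscale) + 1, 1), ncol(zb))
      iv <- pmin(pmax(round(px[, 2] / downscale) + 1, 1), nrow(zb))
      zval <- zb[cbind(iv, iu)]
      # an empty z-buffer cell means nothing renders there: no occluder
      ok <- ok & (!is.finite(zval) | depth <= zval + occlusion_tol_m)
      d <- sqrt(rowSums(view^2))
      dist[ok, k] <- d[ok]
    }
    assign <- matrix(0L, nf, max_views)
    weights <- matrix(0, nf, max_views)
    n_seen <- integer(nf)
    for (f in seq_len(nf)) {
      dd <- dist[f, ]
      vis <- which(is.finite(dd))
      n_seen[f] <- length(vis)
      if (length(vis) == 0) next
      ord <- vis[order(dd[vis], cams[vis])][seq_len(min(max_views, length(vis)))]
      assign[f, seq_along(ord)] <- cams[ord]
      w <- rev(seq_len(max_views))[seq_along(ord)]  # 4,3,2,1
      weights[f, seq_along(ord)] <- w / sum(w)
    }
    out[[band]] <- list(assign = assign, weights = weights, n_seen = n_seen)
  }
  out
}

face_centres <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

# bilinear sample of an image band at pixel coords (0-based)
sample_image <- function(img, px, band = 1) {
  if (length(dim(img)) == 3) img <- img[, , band]
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(px[, 1], 0), w - 1)
  y <- pmin(pmax(px[, 2], 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
}

#' Blend the assigned views at one face
#'
#' Projects a 3D point on the face (default its centroid) into each
#' assigned image and returns the weighted average sample per band: the
#' per-face texel rule used by the orthomosaic renderer, exposed for
#' inspection and testing.  The blend is convex, so values are bounded by
#' the contributing image samples.
#'
#' @param assignment One band's entry from [select_views()].
#' @param images List of image arrays.
#' @param model The `"recon_model"`.
#' @param mesh The mesh.
#' @param face Face index.
#' @param point Optional 3-vector on the face; defaults to the centroid.
#' @return Numeric vector of blended band values, or `NULL` when no view
#'   is assigned.
#' @export
blend_face <- function(assignment, images, model, mesh, face, point = NULL) {
  ids <- assignment$assign[face, ]
  w <- assignment$weights[face, ]
  sel <- ids > 0
  if (!any(sel)) return(NULL)
  if (is.null(point)) point <- face_centres(mesh)[face, ]
  nb <- if (length(dim(images[[ids[sel][1]]])) == 3)
    dim(images[[ids[sel][1]]])[3] else 1L
  acc <- numeric(nb); wsum <- 0
  for (k in which(sel)) {
    i <- ids[k]
    px <- project_points(point, model$poses[[i]], model$intr[[model$body[i]]])
    if (is.na(px[1, 1])) next
    for (b in seq_len(nb))
      acc[b] <- acc[b] + w[k] * sample_image(images[[i]], px, b)
    wsum <- wsum + w[k]
  }
  if (wsum <= 0) return(NULL)
  acc / wsum
}

#' Render colour and near-infrared orthomosaics
#'
#' Orthographic top-down re-rendering of the textured terrain: for every
#' raster cell covered by a face, the cell's 3D position is projected into
#' the (up to four) views assigned to that face in each band and the
#' samples blended with the assignment weights.  Colour and NIR coverage
#' can differ; cells unseen in a band are nodata there.
#'
#' @param mesh Geo-referenced mesh.
#' @param model Matching model.
#' @param images List of image arrays by image id.
#' @param assignments [select_views()] output.
#' @param cell_m Mosaic cell size in metres.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`.
#' @param crs Optional CRS annotation.
#' @return Object of class `"ortho_mosaic"`: [raster_grid()]s `red`,
#'   `green`, `blue`, `nir`, per-band source-count matrices, shared
#'   `origin`/`cell_m`, and the terrain rasters used.
#' @export
render_orthomosaic <- function(mesh, model, images, assignments, cell_m,
                               extent = NULL, crs = NULL) {
  if (length(assignments) == 0) stop("no texture assignments")
  terr <- rasterize_terrain(mesh, cell_m, extent, crs = crs)
  org <- terr$elevation$origin
  grids <- list(); counts <- list()
  for (band in names(assignments)) {
    a <- assignments[[band]]
    ids <- sort(unique(a$assign[a$assign > 0]))
    remap <- match(seq_len(model$n_images), ids)
    assign2 <- matrix(remap[pmax(a$assign, 1L)],
                      nrow(a$assign), ncol(a$assign))
    assign2[is.na(assign2) | a$assign == 0L] <- 0L
    Rs <- lapply(ids, function(i) model$poses[[i]]$R)
    Cs <- lapply(ids, function(i) model$poses[[i]]$centre)
    intrs <- lapply(ids, function(i) {
      ii <- model$intr[[model$body[i]]]
      c(ii$focal, ii$cx, ii$cy, ii$k1, ii$k2)
    })
    imgs <- lapply(ids, function(i) {
      im <- images[[i]]
      if (length(dim(im)) == 2) dim(im) <- c(dim(im), 1)
      im
    })
    nb <- dim(imgs[[1]])[3]
    bl <- blend_mosaic_cpp(terr$face, terr$elevation$values,
                           org[1], org[2], cell_m,
                           assign2, a$weights, imgs, Rs, Cs, intrs,
                           as.integer(nb))
    chan <- if (band == "colour") c("red", "green", "blue") else "nir"
    for (b in seq_along(chan))
      grids[[chan[b]]] <- raster_grid(bl$values[, , b], org, cell_m, crs = crs)
    counts[[band]] <- bl$count
  }
  structure(list(red = grids$red, green = grids$green, blue = grids$blue,
                 nir = grids$nir, counts = counts, origin = org,
                 cell_m = cell_m, terrain = terr),
            class = "ortho_mosaic")
}

#' White-balance gains for the red and near-infrared channels
#'
#' Computes the channel gains that equalise the two cameras' response to a
#' spectrally flat white standard (Spectralon), accounting for the ratio
#' of exposure times: `g_c = (t_white_c / t_survey_c) / W_c`, where `W_c`
#' is the Spectralon channel mean photographed at exposure `t_white_c` and
#' `t_survey_c` the exposure used during the survey.  The defining
#' property (unit-tested): after applying the gains, a spectrally flat
#' surface yields equal balanced values in both channels, hence NDVI 0.
#' Gains are reported normalised so `g_red = 1` (NDVI is invariant to a
#' common positive scaling).
#'
#' @param spectralon Named numeric `c(red=, nir=)` Spectralon channel
#'   means (camera-linear, > 0).
#' @param exposure_survey Named `c(red=, nir=)` survey exposure times
#'   (seconds, > 0).
#' @param exposure_white Exposure times of the Spectralon captures;
#'   defaults to the survey exposures (same capture settings).
#' @return Named numeric `c(red=, nir=)` gains.
#' @export
white_balance_gains <- function(spectralon,
                                exposure_survey = c(red = 1, nir = 1),
                                exposure_white = exposure_survey) {
  ch <- c("red", "nir")
  s <- spectralon[ch]; te <- exposure_survey[ch]; tw <- exposure_white[ch]
  if (any(!is.finite(c(s, te, tw))) || any(c(s, te, tw) <= 0))
    stop("Spectralon values and exposure times must be positive")
  g <- (tw / te) / s
  g <- g / g[["red"]]
  stats::setNames(as.numeric(g), ch)
}

#' Compute an NDVI raster from an orthomosaic
#'
#' `NDVI = (g_nir * NIR - g_red * R) / (g_nir * NIR + g_red * R)` per
#' cell on the shared mosaic grid, using white-balanced red and
#' near-infrared channels.  Cells where either band is nodata, or the
#' balanced denominator does not exceed a small guard, become nodata.
#'
#' @param mosaic An [render_orthomosaic()] result (needs `red` and `nir`).
#' @param gains [white_balance_gains()] result.
#' @param eps Denominator guard.
#' @return A [raster_grid()] of NDVI in `[-1, 1]` with attributes `gains`.
#' @export
compute_ndvi <- function(mosaic, gains = c(red = 1, nir = 1), eps = 1e-12) {
  r <- mosaic$red; n <- mosaic$nir
  if (is.null(r) || is.null(n)) stop("mosaic must contain red and nir bands")
  R <- r$values; N <- n$values
  bad <- R == r$nodata | N == n$nodata
  br <- gains[["red"]] * R
  bn <- gains[["nir"]] * N
  den <- bn + br
  out <- (bn - br) / ifelse(abs(den) > eps, den, NA)
  out[bad | abs(den) <= eps] <- r$nodata
  out[!bad & abs(den) > eps] <- pmin(pmax(out[!bad & abs(den) > eps], -1), 1)
  g <- raster_grid(out, r$origin, r$cell_m, nodata = r$nodata, crs = r$crs)
  attr(g, "gains") <- gains
  g
}

#' Patch statistics for NDVI validation
#'
#' Emulates the manual validation protocol: fixed-size square patches
#' (default 15x15 cells) are extracted from the NDVI raster at given
#' centres with coverage-type labels; per-patch mean and standard
#' deviation are computed, patches touching nodata are excluded with a
#' warning, and per-label aggregates (mean of patch means, sd across
#' patch means) are paired with closed-form predicted NDVI when supplied.
#'
#' @param ndvi A [compute_ndvi()] raster.
#' @param centres Data frame with `cx`, `cy` (1-based raster column/row of
#'   patch centres) and `label`.
#' @param size Patch edge length in cells (odd; default 15).
#' @param predicted Optional named numeric of predicted NDVI per label.
#' @return List: `patches` (per-patch data frame), `by_label` (aggregated,
#'   with `predicted` and `abs_error` columns when predictions given).
#' @export
patch_statistics <- function(ndvi, centres, size = 15, predicted = NULL) {
  stopifnot(size %% 2 == 1)
  hw <- (size - 1) / 2
  v <- ndvi$values
  rows <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(centres))) {
    cx <- centres$cx[i]; cy <- centres$cy[i]
    if (cx - hw < 1 || cx + hw > ncol(v) || cy - hw < 1 || cy + hw > nrow(v)) {
      n_excluded <- n_excluded + 1L
      next
    }
    patch <- v[(cy - hw):(cy + hw), (cx - hw):(cx + hw)]
    if (any(patch == ndvi$nodata) || anyNA(patch)) {
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(label = centres$label[i], cx = cx, cy = cy,
                 mean = mean(patch), sd = stats::sd(patch), n = size^2)
  }
  if (n_excluded > 0)
    warning(n_excluded, " patch(es) excluded (outside raster or overlapping nodata)")
  patches <- do.call(rbind, rows)
  if (is.null(patches))
    return(list(patches = NULL, by_label = NULL))
  agg <- do.call(rbind, lapply(split(patches, patches$label), function(g)
    data.frame(label = g$label[1], n_patches = nrow(g),
               mean = mean(g$mean), sd = stats::sd(g$mean))))
  rownames(agg) <- NULL
  if (!is.null(predicted)) {
    agg$predicted <- predicted[as.character(agg$label)]
    agg$abs_error <- abs(agg$mean - agg$predicted)
  }
  list(patches = patches, by_label = agg)
}
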