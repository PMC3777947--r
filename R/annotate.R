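#' Locate known world points in a reconstruction
#'
#' Emulates the manual identification of ground-control panels and the
#' waterline in a reconstructed pointcloud: each true world point is
#' projected through the *true* camera poses to get the pixel positions
#' where it appears in the images (what an annotator sees), and those
#' pixel observations are then triangulated with the *estimated* poses
#' and intrinsics, yielding the point's position in reconstruction
#' coordinates, including any reconstruction error.
#'
#' @param model Registered `"recon_model"` (estimated poses).
#' @param true_poses List of true [camera_pose()]s by image id.
#' @param true_intr List of true [camera_intrinsics()] per body.
#' @param X n x 3 matrix of true world points.
#' @param max_views Views used per point (nearest to the point).
#' @param margin_px Image-border margin for usable observations.
#' @return n x 3 matrix of reconstruction-frame positions (NA rows where
#'   the point was seen in fewer than two registered images).
#' @export
locate_in_model <- function(model, true_poses, true_intr, X,
                            max_views = 4, margin_px = 12) {
  X <- as.matrix(X)
  reg <- registered_ids(model)
  out <- matrix(NA_real_, nrow(X), 3)
  for (p in seq_len(nrow(X))) {
    obs <- list()
    for (i in reg) {
      ti <- true_intr[[model$body[i]]]
      px <- project_points(X[p, ], true_poses[[i]], ti)
      if (is.na(px[1, 1])) next
      if (px[1, 1] < margin_px || px[1, 1] > ti$width - 1 - margin_px ||
          px[1, 2] < margin_px || px[1, 2] > ti$height - 1 - margin_px) next
      obs[[length(obs) + 1]] <- list(img = i, px = px,
                                     d = attr(px, "depth"))
    }
    if (length(obs) < 2) next
    d <- vapply(obs, `[[`, 0, "d")
    obs <- obs[order(d)][seq_len(min(max_views, length(obs)))]
    imgs <- vapply(obs, `[[`, 0L, "img")
    Rc <- array(0, c(3, 3, length(obs)))
    Cc <- matrix(0, length(obs), 3)
    xn <- matrix(0, length(obs), 2)
    for (k in seq_along(obs)) {
      i <- imgs[k]
      Rc[, , k] <- model$poses[[i]]$R
      Cc[k, ] <- model$poses[[i]]$centre
      xn[k, ] <- undistort_pixels(obs[[k]]$px, model$intr[[model$body[i]]])
    }
    tri <- triangulate_points_cpp(seq_along(obs) - 1L,
                                  rep(0L, length(obs)),
                                  xn[, 1], xn[, 2], Rc, Cc, 1L)
    if (tri$ok[1]) out[p, ] <- tri$X[1, ]
  }
  out
}

#' Attach reconstruction-frame annotations to a GCP table
#'
#' @param gcps GCP data frame (`id`, `triad_id`, `lat`, `lon`, `alt`,
#'   `edge_m`).
#' @param positions n x 3 matrix of reconstruction-frame positions
#'   (`rx`, `ry`, `rz`), row-matched to `gcps`.
#' @return The GCP data frame with `rx`, `ry`, `rz` columns.
#' @export
annotate_gcps <- function(gcps, positions) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == nrow(gcps))
  if (anyNA(positions))
    stop("some GCPs could not be located in the reconstruction")
  gcps$rx <- positions[, 1]
  gcps$ry <- positions[, 2]
  gcps$rz <- positions[, 3]
  gcps
}
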