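#' Plan a zig-zag kite flight over a scene
#'
#' Produces an ordered list of near-nadir camera poses along a serpentine
#' (zig-zag) track across the scene extent, emulating a kite walked along
#' the shoreline at roughly constant altitude.  Small random rotations and
#' translations model kite motion under a self-levelling suspension.
#' Along-track spacing is chosen so that consecutive image footprints
#' overlap by at least the requested fraction.
#'
#' @param scene A [generate_scene()] scene.
#' @param altitude_m Flying height above mean terrain, metres (> 0).
#' @param overlap Required along-track footprint overlap fraction in
#'   `[0, 1)`.
#' @param intr A [camera_intrinsics()]; the footprint is derived from it.
#' @param n_rows Number of serpentine rows across the shore.
#' @param n_views Optional cap on the total number of poses.
#' @param max_tilt_deg Maximum jitter rotation (degrees).
#' @param jitter_xy_m Standard deviation of horizontal position jitter.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return Object of class `"flight_plan"`: list with `poses` (list of
#'   [camera_pose()]), `altitude_m`, `footprint_m` (nominal ground
#'   footprint at the flying height), `overlap`, `intr`.
#' @export
plan_flight <- function(scene, altitude_m = 15, overlap = 0.7,
                        intr = camera_intrinsics(), n_rows = 2,
                        n_views = NULL, max_tilt_deg = 5,
                        jitter_xy_m = 0.25, seed = 1) {
  stopifnot(altitude_m > 0)
  if (overlap >= 1) stop("overlap fraction must be < 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  fp <- c(intr$width, intr$height) / intr$focal * altitude_m
  z0 <- mean(scene$heightfield) + altitude_m
  step <- max(fp[1] * (1 - overlap), 0.5)
  margin_x <- min(fp[1] * 0.45, scene$size_m[1] / 2)
  margin_y <- min(fp[2] * 0.45, scene$size_m[2] / 2)
  # single pass along the shore; the operator walks a zig-zag so the
  # camera crosses the shore width several times while advancing,
  # giving varied perspectives (which is what lets structure-from-motion
  # self-calibrate) rather than a straight line
  span_x <- max(scene$size_m[1] - 2 * margin_x, 0.01)
  y_lo <- margin_y
  y_hi <- max(scene$size_m[2] - margin_y, y_lo + 0.01)
  n_legs <- max(2 * n_rows, 2)
  n <- if (!is.null(n_views)) n_views
       else max(2, ceiling(span_x / step) +
                  ceiling(n_legs * (y_hi - y_lo) /
                            max(fp[2] * (1 - overlap), 0.5)) + 1)
  poses <- vector("list", n)
  for (k in seq_len(n)) {
    t <- (k - 1) / max(n - 1, 1)
    x <- margin_x + t * span_x
    w <- abs(((t * n_legs) %% 2) - 1)   # triangle wave, n_legs crossings
    y <- y_lo + (y_hi - y_lo) * (1 - w)
    C <- c(x + stats::rnorm(1, 0, jitter_xy_m),
           y + stats::rnorm(1, 0, jitter_xy_m),
           z0 + stats::rnorm(1, 0, jitter_xy_m))
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- min(abs(stats::rnorm(1, 0, max_tilt_deg / 2.5)), max_tilt_deg) * pi / 180
    base <- nadir_pose(C, yaw_rad = stats::rnorm(1, 0, 2 * pi / 180))
    poses[[k]] <- camera_pose(rodrigues(ax * ang) %*% base$R, C)
  }
  structure(list(poses = poses, altitude_m = altitude_m,
                 footprint_m = fp, overlap = overlap, intr = intr),
            class = "flight_plan")
}

#' Ground footprint rectangle of a nadir view
#'
#' @param pose A [camera_pose()].
#' @param intr A [camera_intrinsics()].
#' @param ground_z Ground elevation used for the footprint plane.
#' @return Numeric vector `c(xmin, xmax, ymin, ymax)` of the nadir-
#'   approximated footprint on the plane `z = ground_z`.
#' @export
footprint_rect <- function(pose, intr, ground_z = 0) {
  h <- pose$centre[3] - ground_z
  # project image corner rays onto the ground plane
  corners <- rbind(c(0, 0), c(intr$width - 1, 0),
                   c(0, intr$height - 1), c(intr$width - 1, intr$height - 1))
  xy <- undistort_pixels(corners, intr)
  dirs <- t(pose$R) %*% rbind(t(xy), 1)
  tt <- -h / dirs[3, ]
  gx <- pose$centre[1] + tt * dirs[1, ]
  gy <- pose$centre[2] + tt * dirs[2, ]
  c(min(gx), max(gx), min(gy), max(gy))
}
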