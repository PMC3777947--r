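#' Geodetic to local east-north-up conversion
#'
#' A single well-defined tangent-plane mapping anchored at a configurable
#' geodetic origin: east/north offsets are computed from longitude/latitude
#' differences scaled by the WGS84 prime-vertical and meridian radii at the
#' origin latitude; up is the altitude difference.  Altitudes are treated
#' as relative heights (handheld-GPS grade makes the ellipsoid/geoid
#' distinction moot).
#'
#' @param geo n x 3 matrix or data frame of (lat, lon, alt) in degrees /
#'   metres.
#' @param origin Named vector `c(lat, lon, alt)` of the tangent-plane
#'   anchor.
#' @return n x 3 matrix of (east, north, up) in metres.
#' @export
geodetic_to_enu <- function(geo, origin) {
  geo <- as.matrix(geo)
  r <- wgs84_radii(origin[["lat"]])
  cbind(
    east = (geo[, 2] - origin[["lon"]]) * pi / 180 * r$N * cos(origin[["lat"]] * pi / 180),
    north = (geo[, 1] - origin[["lat"]]) * pi / 180 * r$M,
    up = geo[, 3] - origin[["alt"]]
  )
}

#' @rdname geodetic_to_enu
#' @param enu n x 3 matrix of (east, north, up) in metres.
#' @export
enu_to_geodetic <- function(enu, origin) {
  enu <- as.matrix(enu)
  r <- wgs84_radii(origin[["lat"]])
  cbind(
    lat = origin[["lat"]] + enu[, 2] / r$M * 180 / pi,
    lon = origin[["lon"]] + enu[, 1] / (r$N * cos(origin[["lat"]] * pi / 180)) * 180 / pi,
    alt = origin[["alt"]] + enu[, 3]
  )
}

wgs84_radii <- function(lat_deg) {
  a <- 6378137; e2 <- 0.00669437999014
  s2 <- sin(lat_deg * pi / 180)^2
  list(M = a * (1 - e2) / (1 - e2 * s2)^1.5, N = a / sqrt(1 - e2 * s2))
}

#' Similarity transform (scale, rotation, translation)
#'
#' Maps `x -> scale * R %*% x + t`.
#'
#' @param scale Positive scalar.
#' @param R Proper orthonormal 3x3 rotation.
#' @param t Translation 3-vector.
#' @return Object of class `"similarity_transform"`.
#' @export
similarity_transform <- function(scale = 1, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(scale > 0, all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be a proper rotation")
  structure(list(scale = scale, R = R, t = as.numeric(t)),
            class = "similarity_transform")
}

#' Apply or invert a similarity transform
#'
#' @param tf A [similarity_transform()].
#' @param X n x 3 matrix of points (or 3-vector).
#' @return Transformed points (same shape).
#' @export
apply_similarity <- function(tf, X) {
  one <- is.null(dim(X))
  if (one) X <- matrix(X, ncol = 3)
  out <- tf$scale * t(tf$R %*% t(X)) + matrix(tf$t, nrow(X), 3, byrow = TRUE)
  if (one) drop(out) else out
}

#' @rdname apply_similarity
#' @export
invert_similarity <- function(tf) {
  Rin <- t(tf$R)
  similarity_transform(1 / tf$scale, Rin, -Rin %*% tf$t / tf$scale)
}

#' Compose two similarity transforms (`a` after `b`)
#' @param a,b [similarity_transform()] objects.
#' @return The composed transform `x -> a(b(x))`.
#' @export
compose_similarity <- function(a, b) {
  similarity_transform(a$scale * b$scale, a$R %*% b$R,
                       a$scale * as.numeric(a$R %*% b$t) + a$t)
}

#' Absolute scale from GCP triad edge lengths
#'
#' Recovers the absolute scale of a reconstruction from the hand-measured
#' edge lengths of ground-control triads: the scale is the mean, over all
#' within-triad point pairs, of measured length divided by the
#' reconstruction-frame length.
#'
#' @param gcps Data frame with columns `id`, `triad_id`, `edge_m` and
#'   reconstruction-frame positions `rx`, `ry`, `rz`.
#' @return Scalar scale factor (metres per reconstruction unit), with
#'   attribute `"edge_ratios"`.
#' @export
estimate_scale <- function(gcps) {
  stopifnot(all(c("triad_id", "edge_m", "rx", "ry", "rz") %in% names(gcps)))
  ratios <- c()
  for (t in unique(gcps$triad_id)) {
    g <- gcps[gcps$triad_id == t, ]
    if (nrow(g) != 3) stop("each triad must have exactly 3 members")
    P <- as.matrix(g[, c("rx", "ry", "rz")])
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      d <- sqrt(sum((P[pr[1], ] - P[pr[2], ])^2))
      if (d <= 0) stop("zero-length reconstructed triad edge")
      ratios <- c(ratios, g$edge_m[1] / d)
    }
  }
  structure(mean(ratios), edge_ratios = ratios)
}

#' Horn's closed-form absolute orientation
#'
#' Least-squares rotation, translation and (optionally) scale aligning a
#' source point set to a corresponded target set, via the quaternion
#' eigenvalue solution.  Reflections are excluded by construction.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @param estimate_scale_flag If `TRUE`, also estimate a uniform scale;
#'   otherwise scale is fixed at 1.
#' @return A [similarity_transform()] with attribute `"residuals"`
#'   (per-point Euclidean distances after alignment) and `"rmse"`.
#' @export
horn_align <- function(source, target, estimate_scale_flag = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3)
  n <- nrow(source)
  if (n < 3) stop("need at least 3 correspondences")
  sc <- colMeans(source); tc <- colMeans(target)
  S <- sweep(source, 2, sc); T <- sweep(target, 2, tc)
  if (svd(S)$d[2] < 1e-9 * max(svd(S)$d[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  M <- crossprod(S, T)  # sum s_i t_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  R <- quat_to_rot(q)
  s <- 1
  if (estimate_scale_flag) {
    s <- sum(T * t(R %*% t(S))) / sum(S^2)
    if (s <= 0) stop("non-positive scale estimate")
  }
  t_vec <- tc - s * as.numeric(R %*% sc)
  tf <- similarity_transform(s, R, t_vec)
  res <- sqrt(rowSums((apply_similarity(tf, source) - target)^2))
  attr(tf, "residuals") <- res
  attr(tf, "rmse") <- sqrt(mean(res^2))
  tf
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
}

#' Geo-register a reconstruction with ground control points
#'
#' Two-stage geo-registration that separates accuracy sources: first the
#' absolute scale is recovered from tape-measured triad edge lengths
#' ([estimate_scale()]); then, with scale frozen, Horn's method aligns the
#' scaled reconstruction-frame GCP positions to their GPS coordinates
#' converted to local east-north-up.  GPS error therefore affects only the
#' global placement, never the scale (local accuracy) of the model.
#'
#' @param model A reconstruction model (see [run_incremental_sfm()]), or
#'   `NULL` to return just the transform and residual report.
#' @param gcps Data frame with `id`, `triad_id`, `lat`, `lon`, `alt`,
#'   `edge_m` and reconstruction-frame annotations `rx`, `ry`, `rz`.
#' @param origin Geodetic origin `c(lat, lon, alt)` of the ENU frame.
#' @return List with `model` (transformed, or `NULL`), `transform` (the
#'   [similarity_transform()]), and `report`: global residuals (3D and
#'   horizontal mean distance GCP vs transformed position, metres) and the
#'   local residual (mean absolute triad edge-length error, metres).
#' @export
georegister <- function(model, gcps, origin) {
  s <- estimate_scale(gcps)
  src <- as.matrix(gcps[, c("rx", "ry", "rz")]) * as.numeric(s)
  tgt <- geodetic_to_enu(gcps[, c("lat", "lon", "alt")], origin)
  horn <- horn_align(src, tgt, estimate_scale_flag = FALSE)
  tf <- compose_similarity(horn, similarity_transform(as.numeric(s), diag(3), c(0, 0, 0)))
  mapped <- apply_similarity(tf, as.matrix(gcps[, c("rx", "ry", "rz")]))
  d3 <- sqrt(rowSums((mapped - tgt)^2))
  d2 <- sqrt(rowSums((mapped[, 1:2, drop = FALSE] - tgt[, 1:2, drop = FALSE])^2))
  # local residual: measured vs reconstructed (scaled) edge lengths
  edge_err <- c()
  for (t in unique(gcps$triad_id)) {
    g <- gcps[gcps$triad_id == t, ]
    P <- apply_similarity(tf, as.matrix(g[, c("rx", "ry", "rz")]))
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      d <- sqrt(sum((P[pr[1], ] - P[pr[2], ])^2))
      edge_err <- c(edge_err, abs(d - g$edge_m[1]))
    }
  }
  report <- list(scale = as.numeric(s),
                 global_residual_m = mean(d3),
                 global_residual_2d_m = mean(d2),
                 local_residual_m = mean(edge_err),
                 n_gcps = nrow(gcps))
  if (!is.null(model)) model <- transform_model(model, tf)
  list(model = model, transform = tf, report = report)
}

#' Apply a similarity transform to a reconstruction model
#'
#' Transforms all sparse/dense points and camera poses; camera rotations
#' are composed with the transform rotation so that reprojection is
#' preserved.
#'
#' @param model Reconstruction model.
#' @param tf A [similarity_transform()].
#' @return Transformed model.
#' @export
transform_model <- function(model, tf) {
  if (!is.null(model$points) && nrow(model$points) > 0)
    model$points <- apply_similarity(tf, model$points)
  if (!is.null(model$dense) && nrow(model$dense) > 0)
    model$dense <- apply_similarity(tf, model$dense)
  for (i in seq_along(model$poses)) {
    if (is.null(model$poses[[i]])) next
    p <- model$poses[[i]]
    model$poses[[i]] <- camera_pose(p$R %*% t(tf$R),
                                    apply_similarity(tf, p$centre))
  }
  model
}

#' Tidal-datum vertical correction from the waterline
#'
#' Rigidly shifts a geo-referenced model vertically so that the mean
#' elevation of the annotated waterline points equals the known tidal
#' datum height at image capture, improving on the poor vertical accuracy
#' of handheld GPS.
#'
#' @param model Geo-referenced reconstruction model (or `NULL`).
#' @param waterline_points n x 3 matrix of waterline points in the same
#'   (geo-referenced) frame as the model.
#' @param datum_height_m Known water-surface height above the tidal datum
#'   at capture time (metres).
#' @return List with `model` (shifted), `shift_m` (signed vertical shift
#'   applied) and `transform`.
#' @export
adjust_vertical_datum <- function(model, waterline_points, datum_height_m) {
  waterline_points <- as.matrix(waterline_points)
  if (nrow(waterline_points) == 0) {
    warning("empty waterline: no vertical datum adjustment applied")
    return(list(model = model, shift_m = 0,
                transform = similarity_transform()))
  }
  shift <- datum_height_m - mean(waterline_points[, 3])
  tf <- similarity_transform(1, diag(3), c(0, 0, shift))
  if (!is.null(model)) model <- transform_model(model, tf)
  list(model = model, shift_m = shift, transform = tf)
}
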