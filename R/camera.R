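#' Pinhole camera intrinsics with radial distortion
#'
#' Shared intrinsics for one camera body: focal length and principal point
#' in pixels, plus a two-parameter even radial distortion polynomial
#' applied to normalised image coordinates
#' (`x_d = x * (1 + k1 r^2 + k2 r^4)`).
#'
#' Pixel convention: origin at the centre of the top-left pixel, x
#' rightward, y downward, 0-based.
#'
#' @param focal Focal length in pixels (> 0).
#' @param width,height Image size in pixels.
#' @param cx,cy Principal point (defaults to the image centre).
#' @param k1,k2 Radial distortion coefficients.
#' @return Object of class `"camera_intrinsics"`.
#' @export
camera_intrinsics <- function(focal = 436, width = 640, height = 427,
                              cx = (width - 1) / 2, cy = (height - 1) / 2,
                              k1 = 0, k2 = 0) {
  stopifnot(focal > 0, width >= 2, height >= 2)
  structure(list(focal = focal, cx = cx, cy = cy, k1 = k1, k2 = k2,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Rotation matrix from an axis-angle (Rodrigues) vector
#'
#' @param w Numeric 3-vector; direction is the rotation axis, norm the
#'   angle in radians.
#' @return Proper orthonormal 3x3 matrix.
#' @export
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle vector of a rotation matrix
#' @param R Proper orthonormal 3x3 matrix.
#' @return Numeric 3-vector (inverse of [rodrigues()]).
#' @export
rodrigues_inv <- function(R) {
  c_th <- (sum(diag(R)) - 1) / 2
  c_th <- min(1, max(-1, c_th))
  th <- acos(c_th)
  if (th < 1e-9) {
    return(0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    i <- which.max(k)
    k <- A[, i] / k[i]
    return(th * k / sqrt(sum(k^2)))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  th / (2 * sin(th)) * v
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Camera pose (world-to-camera rotation and centre)
#'
#' A camera pose maps a world point `X` to camera coordinates
#' `X_c = R %*% (X - centre)`; the camera looks along +z in its own frame
#' with x rightward and y downward (standard computer-vision convention).
#'
#' @param R Proper orthonormal 3x3 world-to-camera rotation.
#' @param centre Camera centre in world coordinates.
#' @return Object of class `"camera_pose"`.
#' @export
camera_pose <- function(R, centre) {
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be a proper orthonormal rotation")
  structure(list(R = R, centre = as.numeric(centre)), class = "camera_pose")
}

#' Nadir (straight-down) camera pose
#'
#' For a downward-looking aerial camera in an east-north-up world frame:
#' image x maps to east, image y to south (so north is up in the image),
#' optical axis pointing down.
#'
#' @param centre Camera centre (east, north, up), metres.
#' @param yaw_rad Rotation about the vertical axis (radians,
#'   counter-clockwise from east-aligned image x).
#' @return A [camera_pose()].
#' @export
nadir_pose <- function(centre, yaw_rad = 0) {
  base <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(yaw_rad), sin(yaw_rad), 0,
                 -sin(yaw_rad), cos(yaw_rad), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  camera_pose(base %*% Rz, centre)
}

#' Project world points into an image
#'
#' Applies the pose, perspective division, radial distortion and the
#' pixel mapping of the intrinsics.
#'
#' @param X n x 3 matrix of world points (or a 3-vector).
#' @param pose A [camera_pose()].
#' @param intr A [camera_intrinsics()].
#' @return n x 2 matrix of pixel coordinates, with attribute `"depth"`
#'   giving the z-depth of each point in the camera frame (points behind
#'   the camera have negative depth and NA pixels).
#' @export
project_points <- function(X, pose, intr) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  Xc <- t(pose$R %*% (t(X) - pose$centre))
  z <- Xc[, 3]
  x <- Xc[, 1] / z
  y <- Xc[, 2] / z
  r2 <- x^2 + y^2
  d <- 1 + intr$k1 * r2 + intr$k2 * r2^2
  px <- cbind(intr$focal * x * d + intr$cx, intr$focal * y * d + intr$cy)
  px[z <= 0, ] <- NA_real_
  attr(px, "depth") <- z
  px
}

#' Back-project pixels to unit-depth normalised coordinates
#'
#' Inverts the pixel mapping and (iteratively) the radial distortion,
#' returning undistorted normalised coordinates `(x, y)` such that the ray
#' in camera coordinates is `(x, y, 1)`.
#'
#' @param px n x 2 pixel coordinates.
#' @param intr A [camera_intrinsics()].
#' @param iterations Fixed-point iterations for distortion inversion.
#' @return n x 2 normalised coordinates.
#' @export
undistort_pixels <- function(px, intr, iterations = 8) {
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  xd <- (px[, 1] - intr$cx) / intr$focal
  yd <- (px[, 2] - intr$cy) / intr$focal
  x <- xd; y <- yd
  for (i in seq_len(iterations)) {
    r2 <- x^2 + y^2
    d <- 1 + intr$k1 * r2 + intr$k2 * r2^2
    x <- xd / d; y <- yd / d
  }
  cbind(x, y)
}

# distort normalised coordinates (forward model)
distort_normalised <- function(xy, intr) {
  r2 <- xy[, 1]^2 + xy[, 2]^2
  d <- 1 + intr$k1 * r2 + intr$k2 * r2^2
  cbind(xy[, 1] * d, xy[, 2] * d)
}

# 3x3 calibration matrix (no distortion)
intrinsics_matrix <- function(intr) {
  matrix(c(intr$focal, 0, 0, 0, intr$focal, 0, intr$cx, intr$cy, 1), 3, 3)
}
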