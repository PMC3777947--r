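#' Render multispectral views of a synthetic scene
#'
#' Renders every pose of a flight plan through a pinhole camera with radial
#' distortion.  Each pixel's band value is the trapezoidal integral of the
#' surface class reflectance times the channel spectral response, scaled by
#' the camera exposure time and a procedural multiplicative speckle texture
#' (shared across bands, fixed seed) that makes local features detectable;
#' optional Gaussian pixel noise is added.  The colour camera yields
#' three-band images (R, G, B), the near-infrared camera a single band.
#'
#' @param scene A [generate_scene()] scene.
#' @param plan A [plan_flight()] flight plan.
#' @param intr A [camera_intrinsics()] (defaults to the plan's).
#' @param responses Named list of [spectral_response()] objects; for
#'   `band = "colour"` the `red`, `green`, `blue` entries are used, for
#'   `band = "nir"` the `nir` entry (the red Bayer channel of the converted
#'   body).
#' @param band `"colour"` or `"nir"`.
#' @param exposure Exposure-time scale factor applied to all band values
#'   (camera-linear units are arbitrary).
#' @param noise_sd Gaussian pixel noise standard deviation (same units as
#'   pixel values); 0 for noise-free rendering.
#' @param tex_scales,tex_weights,tex_amp Speckle texture octave scales
#'   (metres), weights and amplitude.
#' @param tex_seed,seed Texture / noise seeds.
#' @return List of class `"view_set"`: `images` (list of arrays
#'   `height x width x bands`), `truth` (list with per-image true
#'   [camera_pose()]s, true intrinsics, band label), `band`, `intr`.
#' @export
render_views <- function(scene, plan, intr = plan$intr,
                         responses = default_camera_responses(),
                         band = c("colour", "nir"), exposure = 1,
                         noise_sd = 0,
                         tex_scales = c(0.6, 0.25, 0.12),
                         tex_weights = c(0.5, 0.35, 0.25),
                         tex_amp = 0.35, tex_seed = 99, seed = 1) {
  band <- match.arg(band)
  chans <- if (band == "colour") c("red", "green", "blue") else "nir"
  base <- class_band_values(scene, responses[chans]) * exposure
  cover_idx <- matrix(match(scene$coverage, scene$classes),
                      nrow(scene$coverage), ncol(scene$coverage))
  images <- vector("list", length(plan$poses))
  for (i in seq_along(plan$poses)) {
    p <- plan$poses[[i]]
    images[[i]] <- render_view_cpp(scene$heightfield, scene$cell_m,
                                   cover_idx, base, p$R, p$centre,
                                   intr$focal, intr$cx, intr$cy,
                                   intr$k1, intr$k2, intr$width, intr$height,
                                   tex_scales, tex_weights, tex_amp,
                                   as.integer(tex_seed), noise_sd,
                                   as.integer(seed + i))
  }
  structure(list(images = images, band = band, intr = intr,
                 truth = list(poses = plan$poses, intr = intr, band = band),
                 exposure = exposure, channels = chans),
            class = "view_set")
}

#' Per-class band values (spectrum x response integrals)
#'
#' @param scene A scene.
#' @param responses Named list of [spectral_response()] objects.
#' @return Matrix `n_classes x n_channels` of noise-free camera-linear
#'   band values, rows in `scene$classes` order.
#' @export
class_band_values <- function(scene, responses) {
  vals <- vapply(responses, function(r) {
    vapply(scene$classes, function(cl)
      predict_band_response(scene$class_spectra[[cl]], r)$value, 0)
  }, numeric(length(scene$classes)))
  matrix(vals, nrow = length(scene$classes),
         dimnames = list(scene$classes, names(responses)))
}

#' Simulated Spectralon white-target channel means
#'
#' Emulates photographing a near-perfect diffuse white standard with each
#' camera: the channel mean is the flat-reflectance integral of the channel
#' response times the exposure.
#'
#' @param responses Named list of channel responses.
#' @param exposures Named numeric vector of exposure scales per channel.
#' @param reflectance Spectralon reflectance (default 0.99).
#' @return Named numeric vector of channel means.
#' @export
spectralon_values <- function(responses,
                              exposures = stats::setNames(rep(1, length(responses)),
                                                          names(responses)),
                              reflectance = 0.99) {
  flat <- spectrum(c(350, 850), c(reflectance, reflectance))
  vapply(names(responses), function(ch)
    predict_band_response(flat, responses[[ch]])$value * exposures[[ch]],
    0)
}

#' Image luminance
#'
#' @param img `h x w x bands` array (or matrix).
#' @return `h x w` matrix; multi-band images are averaged over bands.
#' @export
luminance <- function(img) {
  if (length(dim(img)) == 3) {
    out <- img[, , 1]
    if (dim(img)[3] > 1) for (b in 2:dim(img)[3]) out <- out + img[, , b]
    out / dim(img)[3]
  } else img
}

#' Write / read image arrays as TIFF
#'
#' Images are stored as 16-bit TIFF with a fixed linear scaling.
#'
#' @param img `h x w x bands` array with values in `[0, scale]`.
#' @param path Output path.
#' @param scale Value mapped to the maximum code value.
#' @return `read_image_tiff` returns the array scaled back to `[0, scale]`.
#' @export
write_image_tiff <- function(img, path, scale = 1) {
  tiff::writeTIFF(pmin(pmax(img / scale, 0), 1), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 1) {
  img <- tiff::readTIFF(path)
  img * scale
}
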