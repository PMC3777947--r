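#' Reflectance spectrum
#'
#' A reflectance spectrum sampled on a monotone wavelength grid, typically
#' covering the 400--800 nm range of a visible/near-infrared field
#' spectroradiometer.
#'
#' @param wavelength_nm Numeric vector, strictly increasing wavelengths in
#'   nanometres.
#' @param reflectance Numeric vector of dimensionless reflectance values,
#'   nominally in `[0, 1]` (small measurement excursions are tolerated).
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength_nm` and `reflectance`.
#' @export
spectrum <- function(wavelength_nm, reflectance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  stopifnot(length(wavelength_nm) == length(reflectance),
            length(wavelength_nm) >= 2)
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(reflectance)))
    stop("spectrum values must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(reflectance < -0.05) || any(reflectance > 1.1))
    stop("reflectance outside [0,1] beyond measurement tolerance")
  structure(list(wavelength_nm = wavelength_nm, reflectance = reflectance),
            class = "spectrum")
}

#' Camera channel spectral response
#'
#' Per-channel sensitivity versus wavelength, in arbitrary linear camera
#' units.  The near-infrared channel of a converted consumer camera is
#' represented the same way as the red/green/blue channels of the colour
#' body.
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param sensitivity Non-negative sensitivity values.
#' @param channel One of `"red"`, `"green"`, `"blue"`, `"nir"`.
#' @return An object of class `"spectral_response"`.
#' @export
spectral_response <- function(wavelength_nm, sensitivity,
                              channel = c("red", "green", "blue", "nir")) {
  channel <- match.arg(channel)
  wavelength_nm <- as.numeric(wavelength_nm)
  sensitivity <- as.numeric(sensitivity)
  stopifnot(length(wavelength_nm) == length(sensitivity),
            length(wavelength_nm) >= 2)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(sensitivity)) || any(sensitivity < 0))
    stop("sensitivity must be finite and non-negative")
  structure(list(wavelength_nm = wavelength_nm, sensitivity = sensitivity,
                 channel = channel),
            class = "spectral_response")
}

#' Gaussian spectral response curve
#'
#' Convenience constructor for a bell-shaped channel sensitivity, used both
#' to emulate consumer-camera channels (peaks near 470/530/606 nm for the
#' colour body and 740 nm for the near-infrared conversion) and as a known
#' truth in response-estimation tests.
#'
#' @param peak_nm Peak wavelength (nm).
#' @param sigma_nm Gaussian width (nm).
#' @param channel Channel label.
#' @param grid_nm Wavelength grid; default 400--800 nm in 5 nm steps.
#' @param amplitude Peak sensitivity (arbitrary linear units).
#' @return A [spectral_response()].
#' @export
gaussian_response <- function(peak_nm, sigma_nm, channel,
                              grid_nm = seq(400, 800, by = 5),
                              amplitude = 1) {
  s <- amplitude * exp(-0.5 * ((grid_nm - peak_nm) / sigma_nm)^2)
  spectral_response(grid_nm, s, channel)
}

#' Default camera spectral responses
#'
#' The four channels used throughout the pipeline: red, green, blue from the
#' colour camera body with peak sensitivities at 606, 530 and 470 nm, and
#' the near-infrared channel (red Bayer channel of the converted body) with
#' a peak at 740 nm.
#'
#' @param grid_nm Wavelength grid (nm).
#' @return Named list of [spectral_response()] objects
#'   (`red`, `green`, `blue`, `nir`).
#' @export
default_camera_responses <- function(grid_nm = seq(400, 800, by = 5)) {
  list(
    red   = gaussian_response(606, 35, "red",   grid_nm),
    green = gaussian_response(530, 35, "green", grid_nm),
    blue  = gaussian_response(470, 30, "blue",  grid_nm),
    nir   = gaussian_response(740, 30, "nir",   grid_nm)
  )
}

# Linear resampling of (x, y) onto grid `xout`; zero outside support.
resample_linear <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

# Trapezoidal weights for a (possibly irregular) monotone grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

# Union grid over the overlapping support of two monotone grids.
union_grid <- function(a, b) {
  lo <- max(min(a), min(b))
  hi <- min(max(a), max(b))
  if (lo >= hi) stop("wavelength supports are disjoint")
  sort(unique(c(a[a >= lo & a <= hi], b[b >= lo & b <= hi], lo, hi)))
}

#' Predict a camera band response for a reflectance spectrum
#'
#' Computes the camera-linear channel value expected for a surface with the
#' given reflectance spectrum: the spectrum is multiplied by the channel
#' sensitivity and integrated over wavelength (trapezoidal rule on the union
#' grid of the two inputs, both resampled linearly).
#'
#' @param spec A [spectrum()].
#' @param response A [spectral_response()].
#' @return A list with `channel` and non-negative scalar `value`
#'   (class `"band_response"`).
#' @export
predict_band_response <- function(spec, response) {
  stopifnot(inherits(spec, "spectrum"), inherits(response, "spectral_response"))
  g <- union_grid(spec$wavelength_nm, response$wavelength_nm)
  r <- resample_linear(spec$wavelength_nm, spec$reflectance, g)
  s <- resample_linear(response$wavelength_nm, response$sensitivity, g)
  v <- sum(trapezoid_weights(g) * r * s)
  structure(list(channel = response$channel, value = max(v, 0)),
            class = "band_response")
}

#' Integral of a spectral response over wavelength
#'
#' @param response A [spectral_response()].
#' @return Scalar trapezoidal integral of sensitivity over wavelength.
#' @export
response_integral <- function(response) {
  sum(trapezoid_weights(response$wavelength_nm) * response$sensitivity)
}

#' Estimate channel spectral responses from colour-chart panels
#'
#' Recovers a camera channel's sensitivity curve from raw channel values of
#' a set of chart panels with known reflectance spectra (the Macbeth-chart
#' procedure).  For each channel the forward model is
#' `value_p = sum_lambda spectrum_p(lambda) * response(lambda) * dlambda`;
#' the inversion is a non-negative least squares on a regular wavelength
#' grid with a first-difference (Tikhonov) smoothness penalty.
#'
#' @param panel_spectra List of [spectrum()] objects (one per panel).
#' @param panel_values Numeric matrix, one row per panel, one column per
#'   channel (or a vector for a single channel).  Raw camera-linear values.
#' @param channels Character vector of channel labels, one per column.
#' @param smoothness_weight Non-negative smoothness penalty weight; larger
#'   values bias towards flatter curves.
#' @param grid_step_nm Inversion grid step in nm (default 5).
#' @param range_nm Wavelength range of the inversion grid.
#' @return Named list of [spectral_response()] objects with attributes
#'   `residual_norm` (per channel) and `condition` (design condition number).
#' @export
estimate_response <- function(panel_spectra, panel_values,
                              channels = colnames(panel_values),
                              smoothness_weight = 1e-3,
                              grid_step_nm = 5,
                              range_nm = c(400, 800)) {
  if (is.null(dim(panel_values))) panel_values <- cbind(panel_values)
  if (is.null(channels)) channels <- rep(c("red", "green", "blue", "nir"),
                                         length.out = ncol(panel_values))
  stopifnot(length(panel_spectra) == nrow(panel_values),
            smoothness_weight >= 0)
  grid <- seq(range_nm[1], range_nm[2], by = grid_step_nm)
  n <- length(grid)
  # design: one row per panel, trapezoid-weighted resampled spectrum
  w <- trapezoid_weights(grid)
  A <- t(vapply(panel_spectra, function(sp) {
    resample_linear(sp$wavelength_nm, sp$reflectance, grid) * w
  }, numeric(n)))
  sv <- svd(A)$d
  cond <- sv[1] / max(sv[min(nrow(A), n)], .Machine$double.eps)
  eff_rank <- sum(sv > sv[1] * 1e-8)
  if (eff_rank < 3)
    stop(sprintf(
      "panel set is rank-deficient for response estimation (effective rank %d, condition %.3g)",
      eff_rank, cond))
  # first-difference smoothing operator
  D <- diff(diag(n))
  lam <- sqrt(smoothness_weight) * max(abs(A))
  Aaug <- rbind(A, lam * D)
  out <- list()
  res_norm <- numeric(length(channels))
  for (j in seq_along(channels)) {
    b <- c(panel_values[, j], numeric(nrow(D)))
    fit <- pracma::lsqnonneg(Aaug, b)
    out[[channels[j]]] <- spectral_response(grid, fit$x, channels[j])
    res_norm[j] <- sqrt(sum((A %*% fit$x - panel_values[, j])^2))
  }
  names(res_norm) <- channels
  attr(out, "residual_norm") <- res_norm
  attr(out, "condition") <- cond
  out
}

#' Peak wavelength of a spectral response
#'
#' @param response A [spectral_response()].
#' @return Wavelength (nm) of maximum sensitivity.
#' @export
peak_wavelength <- function(response) {
  response$wavelength_nm[which.max(response$sensitivity)]
}

#' Predict NDVI for a reflectance spectrum
#'
#' Predicts the Normalised Difference Vegetation Index a two-camera system
#' would measure for a surface of the given reflectance: the red and
#' near-infrared band responses are computed by spectral integration,
#' white-balance gains applied, and NDVI formed as
#' `(g_nir * NIR - g_red * R) / (g_nir * NIR + g_red * R)`.
#'
#' @param spec A [spectrum()].
#' @param red_resp,nir_resp [spectral_response()] objects for the red and
#'   near-infrared channels.
#' @param wb_gains Optional named numeric vector `c(red=, nir=)` of
#'   white-balance gains (see [white_balance_gains()]); defaults to unity.
#' @return NDVI scalar in `[-1, 1]`.
#' @export
predict_ndvi <- function(spec, red_resp, nir_resp,
                         wb_gains = c(red = 1, nir = 1)) {
  r <- predict_band_response(spec, red_resp)$value * wb_gains[["red"]]
  n <- predict_band_response(spec, nir_resp)$value * wb_gains[["nir"]]
  if (r + n <= 0) stop("undefined NDVI: both balanced band responses are zero")
  unname((n - r) / (n + r))
}

#' Read / write spectra as two-column CSV
#'
#' Plain-text interchange for spectra and responses:
#' columns `wavelength_nm` and `value`.
#'
#' @param path CSV file path.
#' @param x A [spectrum()] or [spectral_response()].
#' @return `read_spectrum_csv` returns a [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  spectrum(d[[1]], d[[2]])
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(x, path) {
  v <- if (inherits(x, "spectrum")) x$reflectance else x$sensitivity
  utils::write.csv(data.frame(wavelength_nm = x$wavelength_nm, value = v),
                   path, row.names = FALSE)
  invisible(path)
}
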