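#' Coverage-class reflectance spectra for an intertidal shore
#'
#' Builds smooth reflectance spectra for the dominant coverage types of a
#' temperate rocky shore: dry and wet rock, sand, green/brown/red
#' macroalgae, cunjevoi (tunicate mats) and water.  The algal spectra carry
#' the chlorophyll signature (strong red absorption, sharp red-edge near
#' 700 nm rising to a near-infrared plateau); rock and sand are spectrally
#' flat to gently sloped; water absorbs strongly in the near-infrared.
#'
#' @param grid_nm Wavelength grid in nm.
#' @return Named list of [spectrum()] objects.
#' @export
intertidal_class_spectra <- function(grid_nm = seq(400, 800, by = 5)) {
  g <- grid_nm
  sigmoid <- function(x) 1 / (1 + exp(-x))
  red_edge <- function(vis, nir, edge_nm = 700, width_nm = 12)
    vis + (nir - vis) * sigmoid((g - edge_nm) / width_nm)
  green_bump <- function(amp, centre = 550, width = 30)
    amp * exp(-0.5 * ((g - centre) / width)^2)
  list(
    dry_rock    = spectrum(g, rep(0.30, length(g))),
    wet_rock    = spectrum(g, 0.12 + 0.00005 * (g - 400)),
    sand        = spectrum(g, 0.25 + 0.0004 * (g - 400)),
    green_algae = spectrum(g, pmin(1, red_edge(0.05, 0.48) + green_bump(0.10))),
    brown_algae = spectrum(g, pmin(1, red_edge(0.07, 0.32) + green_bump(0.04, 580, 40))),
    red_algae   = spectrum(g, pmin(1, red_edge(0.06, 0.26) + green_bump(0.05, 620, 25))),
    cunjevoi    = spectrum(g, 0.16 + 0.0001 * (g - 400)),
    water       = spectrum(g, pmax(0.002, 0.055 - 0.053 * sigmoid((g - 680) / 15)))
  )
}

# smooth value-noise field on an ny x nx grid: sum of bilinearly
# upsampled Gaussian lattices at the given lattice spacings (in cells)
smooth_noise_field <- function(ny, nx, spacings, weights) {
  out <- matrix(0, ny, nx)
  for (k in seq_along(spacings)) {
    sp <- spacings[k]
    cy <- max(2, ceiling(ny / sp) + 1)
    cx <- max(2, ceiling(nx / sp) + 1)
    coarse <- matrix(stats::rnorm(cy * cx), cy, cx)
    yi <- (seq_len(ny) - 1) / sp + 1
    xi <- (seq_len(nx) - 1) / sp + 1
    y0 <- pmin(floor(yi), cy - 1); x0 <- pmin(floor(xi), cx - 1)
    fy <- yi - y0; fx <- xi - x0
    # smoothstep for C1 continuity
    fy <- fy * fy * (3 - 2 * fy); fx <- fx * fx * (3 - 2 * fx)
    up <- coarse[y0, x0] * outer(1 - fy, 1 - fx) +
      coarse[y0 + 1, x0] * outer(fy, 1 - fx) +
      coarse[y0, x0 + 1] * outer(1 - fy, fx) +
      coarse[y0 + 1, x0 + 1] * outer(fy, fx)
    out <- out + weights[k] * up
  }
  out
}

#' Generate a synthetic intertidal scene
#'
#' Builds a deterministic synthetic shore: a smooth heightfield (octaves of
#' band-limited noise on a cross-shore ramp, with carved rock-pool
#' depressions), a contiguous coverage-class map, per-class reflectance
#' spectra and a tidal water datum.  Cells below the water datum are
#' labelled water; remaining classes form contiguous patches driven by
#' smooth random fields with elevation preferences (algae low on the shore,
#' dry rock high).
#'
#' @param size_m Plan extent `c(x_east, y_north)` in metres (positive).
#' @param cell_m Heightfield cell size in metres.
#' @param n_classes Number of non-water coverage classes to use (1--7).
#' @param relief_m Peak-to-peak scale of terrain relief in metres.
#' @param water_datum Water surface elevation (m above tidal datum);
#'   default 0.16 m, a typical low-tide height.
#' @param n_pools Number of carved rock-pool depressions.
#' @param geodetic_origin Named vector `c(lat, lon, alt)` anchoring the
#'   local east-north-up frame.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#' @return An object of class `"scene"`.
#' @export
generate_scene <- function(size_m = c(45, 25), cell_m = 0.1, n_classes = 6,
                           relief_m = 2.2, water_datum = 0.16, n_pools = 6,
                           geodetic_origin = c(lat = -35.0857, lon = 150.6933, alt = 0),
                           seed = 1) {
  stopifnot(length(size_m) == 2, cell_m > 0)
  if (any(size_m <= 0)) stop("degenerate extent: size_m must be positive")
  n_classes <- max(1, min(7, n_classes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nx <- max(4, round(size_m[1] / cell_m) + 1)
  ny <- max(4, round(size_m[2] / cell_m) + 1)
  x <- (seq_len(nx) - 1) * cell_m
  y <- (seq_len(ny) - 1) * cell_m

  # cross-shore ramp: seaward (south, y = 0) below datum, landward above
  ramp <- matrix(rep(-0.6 + 3.0 * y / max(y), nx), ny, nx)
  octaves <- smooth_noise_field(ny, nx,
                                spacings = c(80, 30, 12, 5) / (cell_m / 0.1),
                                weights = c(0.55, 0.3, 0.12, 0.04))
  z <- ramp + relief_m * 0.5 * octaves
  # carved pool depressions on the mid/upper shore
  for (i in seq_len(n_pools)) {
    px <- stats::runif(1, 0.1, 0.9) * size_m[1]
    py <- stats::runif(1, 0.45, 0.9) * size_m[2]
    pr <- stats::runif(1, 0.8, 2.0)
    pd <- stats::runif(1, 0.2, 0.5)
    d2 <- outer((y - py)^2, (x - px)^2, "+")
    z <- z - pd * exp(-d2 / (2 * (pr / 2)^2))
  }

  classes <- c("dry_rock", "wet_rock", "green_algae", "brown_algae",
               "red_algae", "cunjevoi", "sand")[seq_len(n_classes)]
  spectra <- intertidal_class_spectra()
  if (n_classes == 1) {
    # single flat-reflectance class, for degenerate-scene tests
    classes <- "uniform"
    spectra <- list(uniform = spectrum(seq(400, 800, 5), rep(0.5, 81)),
                    water = spectra$water)
  } else {
    spectra <- spectra[c(classes, "water")]
  }

  # class score fields: smooth noise + elevation preference
  pref <- list(dry_rock = function(e) 0.8 * (e - 1.2),
               wet_rock = function(e) 0.5 - 0.8 * abs(e - 0.6),
               green_algae = function(e) 0.5 - 1.0 * abs(e - 0.35),
               brown_algae = function(e) 0.45 - 1.0 * abs(e - 0.45),
               red_algae = function(e) 0.4 - 1.0 * abs(e - 0.3),
               cunjevoi = function(e) 0.35 - 1.2 * abs(e - 0.25),
               sand = function(e) 0.3 - 0.9 * abs(e - 0.9),
               uniform = function(e) 1)
  scores <- array(0, c(ny, nx, length(classes)))
  for (k in seq_along(classes)) {
    f <- smooth_noise_field(ny, nx, spacings = c(60, 25) / (cell_m / 0.1),
                            weights = c(0.8, 0.35))
    scores[, , k] <- f + pref[[classes[k]]](z)
  }
  cov_idx <- apply(scores, c(1, 2), which.max)
  coverage <- matrix(classes[cov_idx], ny, nx)
  coverage[z < water_datum] <- "water"

  structure(list(
    heightfield = z, coverage = coverage, cell_m = cell_m,
    size_m = size_m, x = x, y = y,
    classes = c(classes, "water"), class_spectra = spectra,
    water_datum = water_datum, geodetic_origin = geodetic_origin,
    seed = seed
  ), class = "scene")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Bilinear elevation lookup on a scene heightfield
#'
#' @param scene A [generate_scene()] scene.
#' @param x,y Plan coordinates in metres (east, north).
#' @return Elevation in metres (vectorised); coordinates outside the extent
#'   are clamped to the boundary.
#' @export
scene_elevation <- function(scene, x, y) {
  bilinear_grid(scene$heightfield, scene$cell_m, x, y)
}

# clamped bilinear interpolation on grid[iy, ix] with spacing cell
bilinear_grid <- function(grid, cell, x, y) {
  dm <- dim(x)
  x <- as.numeric(x); y <- as.numeric(y)
  ny <- nrow(grid); nx <- ncol(grid)
  xi <- pmin(pmax(x / cell, 0), nx - 1)
  yi <- pmin(pmax(y / cell, 0), ny - 1)
  x0 <- pmin(floor(xi), nx - 2); y0 <- pmin(floor(yi), ny - 2)
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(y0 + 1, x0 + 1); i10 <- cbind(y0 + 2, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2); i11 <- cbind(y0 + 2, x0 + 2)
  out <- grid[i00] * (1 - fx) * (1 - fy) + grid[i10] * (1 - fx) * fy +
    grid[i01] * fx * (1 - fy) + grid[i11] * fx * fy
  if (!is.null(dm)) dim(out) <- dm
  out
}

#' Coverage class at plan coordinates
#'
#' @inheritParams scene_elevation
#' @return Character vector of class labels (nearest-cell lookup).
#' @export
scene_class <- function(scene, x, y) {
  nx <- ncol(scene$coverage); ny <- nrow(scene$coverage)
  ix <- pmin(pmax(round(x / scene$cell_m), 0), nx - 1) + 1
  iy <- pmin(pmax(round(y / scene$cell_m), 0), ny - 1) + 1
  scene$coverage[cbind(iy, ix)]
}

#' Extract the waterline contour of a scene
#'
#' Traces the elevation contour at the scene's water datum, emulating the
#' manual extraction of the visible waterline from a reconstructed
#' pointcloud.  Points are returned in the scene (east, north, up) frame
#' with elevation exactly at the datum.
#'
#' @param scene A scene.
#' @param max_points Optional subsampling cap on returned points.
#' @return Data frame with columns `x`, `y`, `z`.
#' @export
extract_waterline <- function(scene, max_points = 500) {
  z <- scene$heightfield
  if (all(z >= scene$water_datum))
    stop("scene is fully dry: no waterline to extract")
  cl <- grDevices::contourLines(x = scene$y, y = scene$x, z = z,
                                levels = scene$water_datum)
  if (length(cl) == 0) stop("no waterline contour found")
  pts <- do.call(rbind, lapply(cl, function(cc)
    cbind(x = cc$y, y = cc$x)))
  if (nrow(pts) > max_points) {
    idx <- round(seq(1, nrow(pts), length.out = max_points))
    pts <- pts[idx, , drop = FALSE]
  }
  data.frame(x = pts[, "x"], y = pts[, "y"], z = scene$water_datum)
}

#' Place ground-control-point triads on a synthetic scene
#'
#' Emulates checkerboard ground-control panels laid out in equilateral
#' triangles ("triads") of tape-measured edge length on dry rock, with
#' handheld-GPS-grade noise on the geodetic coordinates.  The true
#' east-north-up positions are retained for test oracles.
#'
#' @param scene A scene.
#' @param n_triads Number of triads (> 0); each contributes 3 GCPs.
#' @param edge_m Plan edge length of each triangle in metres.
#' @param gps_noise_sd_m Per-axis standard deviation of the simulated GPS
#'   error in metres (vertical noise is 1.5x).
#' @param seed Integer seed.
#' @return List with `gcps` (data frame: id, triad_id, lat, lon, alt,
#'   edge_m), and `truth` (data frame of true ENU positions x, y, z).
#' @export
place_gcps <- function(scene, n_triads = 3, edge_m = 2,
                       gps_noise_sd_m = 1.2, seed = 1) {
  if (n_triads <= 0) stop("n_triads must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  margin <- min(edge_m + 3, scene$size_m[1] / 3)
  centres_x <- seq(margin, scene$size_m[1] - margin,
                   length.out = max(n_triads, 2))[seq_len(n_triads)]
  r <- edge_m / sqrt(3)  # circumradius of the equilateral triangle
  pos <- NULL
  for (t in seq_len(n_triads)) {
    placed <- FALSE
    for (attempt in 1:200) {
      cx <- centres_x[t] + stats::runif(1, -1, 1)
      cy <- stats::runif(1, 0.45, 0.82) * scene$size_m[2]
      ang <- stats::runif(1, 0, 2 * pi)
      # the tape fixes the 3D panel separation: build the equilateral
      # triangle in the local tangent plane of the terrain, so pairwise
      # 3D distances equal edge_m exactly and panels sit on (slightly
      # smoothed) ground
      h <- 0.5
      gx <- (scene_elevation(scene, cx + h, cy) -
               scene_elevation(scene, cx - h, cy)) / (2 * h)
      gy <- (scene_elevation(scene, cx, cy + h) -
               scene_elevation(scene, cx, cy - h)) / (2 * h)
      e1 <- c(1, 0, gx); e1 <- e1 / sqrt(sum(e1^2))
      n <- c(-gx, -gy, 1); n <- n / sqrt(sum(n^2))
      e2 <- c(n[2] * e1[3] - n[3] * e1[2],
              n[3] * e1[1] - n[1] * e1[3],
              n[1] * e1[2] - n[2] * e1[1])
      cz <- scene_elevation(scene, cx, cy)
      P <- t(sapply(ang + c(0, 2, 4) * pi / 3, function(a)
        c(cx, cy, cz) + r * cos(a) * e1 + r * sin(a) * e2))
      if (all(scene_class(scene, P[, 1], P[, 2]) != "water") &&
          all(P[, 3] > scene$water_datum) &&
          max(abs(P[, 3] - scene_elevation(scene, P[, 1], P[, 2]))) < 0.3) {
        pos <- rbind(pos, cbind(triad = t, x = P[, 1], y = P[, 2],
                                z = P[, 3]))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place triad on non-water cells")
  }
  truth <- data.frame(id = seq_len(nrow(pos)), triad_id = pos[, "triad"],
                      x = pos[, "x"], y = pos[, "y"], z = pos[, "z"])
  noisy <- cbind(truth$x + stats::rnorm(nrow(pos), 0, gps_noise_sd_m),
                 truth$y + stats::rnorm(nrow(pos), 0, gps_noise_sd_m),
                 truth$z + stats::rnorm(nrow(pos), 0, 1.5 * gps_noise_sd_m))
  geo <- enu_to_geodetic(noisy, scene$geodetic_origin)
  gcps <- data.frame(id = truth$id, triad_id = truth$triad_id,
                     lat = geo[, 1], lon = geo[, 2], alt = geo[, 3],
                     edge_m = edge_m)
  list(gcps = gcps, truth = truth)
}
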