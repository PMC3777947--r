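#' Triangulate a 2.5D terrain surface from a pointcloud
#'
#' Builds a triangulated terrain model by Delaunay triangulation in the
#' horizontal plane with vertex elevations lifted.  Near-duplicate plan
#' positions are optionally collapsed by gridded aggregation (mean plan
#' position, median elevation per cell), and faces with edges much longer
#' than typical (bridges across data gaps) are removed.
#'
#' @param points n x 3 matrix of (east, north, up) points.
#' @param grid_m Optional decimation cell size in metres; `NULL` keeps all
#'   points (exact duplicates still collapse).
#' @param max_edge_factor Faces with any plan edge longer than this factor
#'   times the median edge length are dropped.
#' @param outlier_filter Optional robust elevation filter applied before
#'   triangulation: a list with `cell` (neighbourhood size, metres) and
#'   `max_dev` (maximum allowed deviation from the neighbourhood median
#'   elevation, metres).  `NULL` disables filtering.
#' @return Object of class `"terrain_mesh"`: `vertices` (n x 3), `faces`
#'   (m x 3, 1-based), `normals` (m x 3 unit east/north/up, upward),
#'   `degenerate` (logical per face).
#' @export
triangulate_surface <- function(points, grid_m = NULL, max_edge_factor = 10,
                                outlier_filter = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (!is.null(outlier_filter)) {
    cell <- outlier_filter$cell %||% 0.25
    max_dev <- outlier_filter$max_dev %||% 0.2
    min_support <- outlier_filter$min_support %||% 3
    key <- paste(floor(points[, 1] / cell), floor(points[, 2] / cell))
    med <- stats::ave(points[, 3], key, FUN = stats::median)
    n_cell <- stats::ave(points[, 3], key, FUN = length)
    points <- points[abs(points[, 3] - med) <= max_dev &
                       n_cell >= min_support, , drop = FALSE]
  }
  if (!is.null(grid_m)) {
    ix <- floor(points[, 1] / grid_m)
    iy <- floor(points[, 2] / grid_m)
    key <- paste(ix, iy)
    sp <- split(seq_len(nrow(points)), key)
    points <- t(vapply(sp, function(idx)
      c(mean(points[idx, 1]), mean(points[idx, 2]),
        stats::median(points[idx, 3])), numeric(3)))
  } else {
    points <- points[!duplicated(points[, 1:2, drop = FALSE]), , drop = FALSE]
  }
  if (nrow(points) < 3) stop("need at least 3 distinct plan positions")
  s <- svd(scale(points[, 1:2], scale = FALSE))$d
  if (s[2] < 1e-9 * max(s[1], 1e-300)) stop("collinear point set")
  # spatially coherent insertion order keeps location walks short
  ord <- order(floor(points[, 2] / max(diff(range(points[, 1])) / 32, 1e-9)),
               points[, 1])
  points <- points[ord, , drop = FALSE]
  F <- delaunay_cpp(points[, 1], points[, 2])
  mesh <- structure(list(vertices = points, faces = F), class = "terrain_mesh")
  mesh <- compute_face_normals(mesh)
  # long-edge filter
  e1 <- edge_len(points, F[, 1], F[, 2])
  e2 <- edge_len(points, F[, 2], F[, 3])
  e3 <- edge_len(points, F[, 1], F[, 3])
  med <- stats::median(c(e1, e2, e3))
  keep <- pmax(e1, e2, e3) <= max_edge_factor * med
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh$normals <- mesh$normals[keep, , drop = FALSE]
  mesh$degenerate <- mesh$degenerate[keep]
  mesh
}

edge_len <- function(V, a, b)
  sqrt(rowSums((V[a, 1:2, drop = FALSE] - V[b, 1:2, drop = FALSE])^2))

compute_face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  u <- B - A; v <- C - A
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  mesh$degenerate <- len < 1e-12
  len[mesh$degenerate] <- 1
  n <- n / len
  flip <- n[, 3] < 0
  n[flip, ] <- -n[flip, ]
  mesh$normals <- n
  mesh
}

#' Per-face slope and aspect from surface normals
#'
#' Slope and aspect of each triangular face from its unit normal with
#' north, east, down components `(n_N, n_E, n_D)` (the package stores
#' east/north/up; the conversion is internal): slope
#' `= arccos(-n_D)` in `[0, 90)` degrees, and aspect `= atan2(n_E, n_N)`
#' mapped to `[0, 360)` degrees clockwise from north.  Horizontal faces
#' have undefined aspect (`NA`); degenerate faces are flagged `NA` in
#' both.
#'
#' @param mesh A [triangulate_surface()] mesh.
#' @param horiz_tol_deg Faces with slope below this are treated as
#'   horizontal (aspect undefined).
#' @return Data frame with `slope_deg`, `aspect_deg`.
#' @export
face_slope_aspect <- function(mesh, horiz_tol_deg = 1e-6) {
  n <- mesh$normals
  n_up <- pmin(pmax(n[, 3], -1), 1)
  slope <- acos(n_up) * 180 / pi       # -n_D = n_up
  aspect <- atan2(n[, 1], n[, 2]) * 180 / pi  # atan2(east, north)
  aspect <- (aspect + 360) %% 360
  aspect[slope < horiz_tol_deg] <- NA_real_
  slope[mesh$degenerate] <- NA_real_
  aspect[mesh$degenerate] <- NA_real_
  data.frame(slope_deg = slope, aspect_deg = aspect)
}

#' Geo-referenced raster grid
#'
#' Lightweight single-band raster: matrix of values (row 1 = southernmost
#' row), plan origin of the cell-centre grid, cell size, nodata marker.
#'
#' @param values Numeric matrix (rows = northing index, cols = easting).
#' @param origin `c(x0, y0)` of the first cell centre (metres ENU).
#' @param cell_m Cell size (metres).
#' @param nodata Nodata marker (default -9999).
#' @param crs Optional list describing the geodetic origin of the ENU
#'   frame.
#' @return Object of class `"raster_grid"`.
#' @export
raster_grid <- function(values, origin, cell_m, nodata = -9999, crs = NULL) {
  stopifnot(is.matrix(values), cell_m > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_m = cell_m, nodata = nodata, crs = crs),
            class = "raster_grid")
}

#' Rasterise a terrain mesh into elevation, slope and aspect grids
#'
#' Per-cell elevation is barycentric interpolation over the covering face;
#' slope and aspect are taken from the covering face; cells outside the
#' triangulation get the nodata value.
#'
#' @param mesh A [triangulate_surface()] mesh.
#' @param cell_m Raster cell size (metres, > 0).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   mesh bounding box.
#' @param crs Optional CRS annotation carried into the rasters.
#' @return Named list of [raster_grid()]s: `elevation`, `slope`, `aspect`,
#'   plus `face` (integer face-id matrix, 0 outside coverage).
#' @export
rasterize_terrain <- function(mesh, cell_m, extent = NULL, crs = NULL) {
  stopifnot(cell_m > 0)
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  sa <- face_slope_aspect(mesh)
  V <- mesh$vertices
  if (is.null(extent))
    extent <- c(min(V[, 1]), max(V[, 1]), min(V[, 2]), max(V[, 2]))
  nx <- max(2, floor((extent[2] - extent[1]) / cell_m) + 1)
  ny <- max(2, floor((extent[4] - extent[3]) / cell_m) + 1)
  slope_in <- sa$slope_deg
  aspect_in <- sa$aspect_deg
  slope_in[is.na(slope_in)] <- -9999
  aspect_in[is.na(aspect_in)] <- -9999
  rr <- rasterize_mesh_cpp(V, mesh$faces, slope_in, aspect_in,
                           extent[1], extent[3], cell_m,
                           as.integer(nx), as.integer(ny))
  org <- c(extent[1], extent[3])
  list(elevation = raster_grid(rr$elevation, org, cell_m, crs = crs),
       slope = raster_grid(rr$a, org, cell_m, crs = crs),
       aspect = raster_grid(rr$b, org, cell_m, crs = crs),
       face = rr$face)
}

#' Sample a raster grid at plan coordinates (nearest cell)
#'
#' @param r A [raster_grid()].
#' @param x,y Coordinates (metres).
#' @return Values (NA where nodata or outside).
#' @export
raster_sample <- function(r, x, y) {
  ix <- round((x - r$origin[1]) / r$cell_m) + 1
  iy <- round((y - r$origin[2]) / r$cell_m) + 1
  ok <- ix >= 1 & ix <= ncol(r$values) & iy >= 1 & iy <= nrow(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(iy[ok], ix[ok])]
  out[!is.na(out) & out == r$nodata] <- NA_real_
  out
}

#' Write a raster as TIFF with a world file
#'
#' Writes the raster as a 32-bit float TIFF plus an ESRI world file
#' (`.tfw`) and a JSON sidecar carrying the nodata marker and the
#' geodetic origin of the local ENU frame, so GIS tools can place it.
#'
#' @param r A [raster_grid()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  v <- r$values
  # TIFF rows run top-down; our rows run south to north
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  rng <- range(v[v != r$nodata])
  if (!all(is.finite(rng))) rng <- c(0, 1)
  scaled <- (v - rng[1]) / max(rng[2] - rng[1], 1e-12)
  scaled[v == r$nodata] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, reduce = TRUE)
  tfw <- sub("\\.tiff?$", ".tfw", path)
  writeLines(format(c(r$cell_m, 0, 0, -r$cell_m,
                      r$origin[1],
                      r$origin[2] + (nrow(r$values) - 1) * r$cell_m),
                    scientific = FALSE), tfw)
  meta <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(nodata = r$nodata, value_range = rng,
                            cell_m = r$cell_m, origin = r$origin,
                            crs = r$crs),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
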