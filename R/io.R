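#' Write a pointcloud as ASCII PLY
#'
#' @param X n x 3 matrix of points.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply_points <- function(X, path) {
  X <- as.matrix(X)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(X)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(X, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a terrain mesh as ASCII PLY
#'
#' @param mesh A [triangulate_surface()] mesh.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply_mesh <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  utils::write.table(format(V, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, F - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a reconstruction model to JSON
#'
#' Poses and intrinsics only (pointclouds go to PLY via
#' [write_ply_points()]).
#'
#' @param model A `"recon_model"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  reg <- registered_ids(model)
  jsonlite::write_json(list(
    n_images = model$n_images,
    registered = reg,
    body = model$body,
    rmse_px = model$rmse,
    intrinsics = lapply(model$intr, function(ii)
      list(focal = ii$focal, cx = ii$cx, cy = ii$cy, k1 = ii$k1,
           k2 = ii$k2, width = ii$width, height = ii$height)),
    poses = lapply(reg, function(i)
      list(image = i, R = model$poses[[i]]$R,
           centre = model$poses[[i]]$centre))
  ), path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Write / read GCP tables and waterline CSV
#'
#' Interchange formats: GCPs as `id, triad_id, lat, lon, alt, edge_m`
#' (plus `rx, ry, rz` when annotated); waterline as `x, y, z` points.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return Read functions return data frames.
#' @export
write_gcp_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gcp_csv
#' @export
read_gcp_csv <- function(path) utils::read.csv(path)
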