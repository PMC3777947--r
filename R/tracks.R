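#' Chain pairwise matches into multi-image tracks
#'
#' Builds the track graph: connected components of the inlier match graph
#' over (image, keypoint) observations, each component corresponding to
#' one physical 3D point.  Tracks containing two different keypoints from
#' the same image are inconsistent and dropped.  Per-track band coverage
#' (colour / NIR / both) is recorded when band labels are supplied.
#'
#' @param matches List of `pair_matches` from [match_all_pairs()] (only
#'   inlier correspondences are used).
#' @param features List of feature sets (for keypoint lookup).
#' @param bands Optional band label per image id.
#' @param min_length Minimum number of observations per track.
#' @return Object of class `"track_graph"`: `tracks` (list of data frames
#'   with `img`, `kp`, `x`, `y`), `band_coverage` (factor per track:
#'   `colour`, `nir`, `both`), `n_dropped` (conflicting tracks removed).
#' @export
build_tracks <- function(matches, features, bands = NULL, min_length = 2) {
  edges_a <- integer(0); edges_b <- integer(0)
  key <- function(img, kp) paste0(img, ":", kp)
  for (m in matches) {
    if (m$status != "matched") next
    ia <- m$idx_a[m$inlier]; ib <- m$idx_b[m$inlier]
    edges_a <- c(edges_a, key(m$img_a, ia))
    edges_b <- c(edges_b, key(m$img_b, ib))
  }
  if (length(edges_a) == 0)
    return(structure(list(tracks = list(), band_coverage = factor(),
                          n_dropped = 0L), class = "track_graph"))
  g <- igraph::graph_from_edgelist(cbind(edges_a, edges_b), directed = FALSE)
  comp <- igraph::components(g)
  verts <- igraph::V(g)$name
  parts <- strsplit(verts, ":", fixed = TRUE)
  img <- vapply(parts, function(p) as.integer(p[1]), 0L)
  kp <- vapply(parts, function(p) as.integer(p[2]), 0L)
  tracks <- list(); coverage <- character(); dropped <- 0L
  ord <- order(comp$membership)
  bounds <- c(0, cumsum(comp$csize))
  img_o <- img[ord]; kp_o <- kp[ord]
  for (t in seq_len(comp$no)) {
    idx <- (bounds[t] + 1):bounds[t + 1]
    ti <- img_o[idx]; tk <- kp_o[idx]
    if (length(idx) < min_length) next
    if (anyDuplicated(ti)) { dropped <- dropped + 1L; next }
    o <- order(ti)
    ti <- ti[o]; tk <- tk[o]
    xy <- t(vapply(seq_along(ti), function(i)
      features[[ti[i]]]$keypoints[tk[i], ], numeric(2)))
    tracks[[length(tracks) + 1]] <-
      data.frame(img = ti, kp = tk, x = xy[, 1], y = xy[, 2])
    if (!is.null(bands)) {
      bb <- unique(bands[ti])
      coverage <- c(coverage,
                    if (length(bb) > 1) "both" else bb)
    }
  }
  structure(list(tracks = tracks,
                 band_coverage = factor(coverage,
                                        levels = c("colour", "nir", "both")),
                 n_dropped = dropped),
            class = "track_graph")
}
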