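#' Extract local invariant features from an image
#'
#' Detects corner features (Harris response on a smoothed image, non-max
#' suppression, subpixel quadratic refinement) and computes upright
#' SIFT-style descriptors: 4x4 spatial cells of 8-bin gradient-orientation
#' histograms, Gaussian-weighted, L2-normalised, clipped at 0.2 and
#' renormalised.  Descriptors are contrast-invariant, which is what makes
#' cross-band (colour vs near-infrared) matching possible.
#'
#' @param img Image: `h x w` matrix or `h x w x bands` array (converted to
#'   luminance).
#' @param id Image identifier stored with the feature set.
#' @param rel_thresh Harris response threshold relative to the image
#'   maximum.
#' @param nms_radius Non-max suppression radius (pixels).
#' @param max_features Cap on the number of features (strongest kept).
#' @param sigma Detection smoothing scale (pixels).
#' @return Object of class `"feature_set"`: `id`, `keypoints` (n x 2, 0-based
#'   pixel x, y), `descriptors` (n x 128, unit L2 norm), `response`.
#'   A featureless (constant) image yields an empty set with a warning.
#' @export
extract_features <- function(img, id = NA_integer_, rel_thresh = 1e-6,
                             nms_radius = 3, max_features = 1500,
                             sigma = 1.2) {
  lum <- luminance(img)
  if (max(lum) - min(lum) < 1e-12) {
    warning("featureless (constant) image: no features extracted")
    return(structure(list(id = id, keypoints = matrix(0, 0, 2),
                          descriptors = matrix(0, 0, 128),
                          response = numeric(0)),
                     class = "feature_set"))
  }
  ft <- detect_features_cpp(lum, sigma = sigma, rel_thresh = rel_thresh,
                            nms_radius = nms_radius,
                            max_features = max_features)
  structure(list(id = id, keypoints = ft$keypoints,
                 descriptors = ft$descriptors, response = ft$response),
            class = "feature_set")
}

#' Match two feature sets
#'
#' Candidate correspondences are mutual nearest neighbours in descriptor
#' space that pass Lowe's ratio test: the nearest-neighbour descriptor
#' distance must be below `ratio` times the second-nearest.  The result is
#' symmetric (matching a to b equals matching b to a up to column order).
#'
#' @param a,b [extract_features()] feature sets.
#' @param ratio Lowe ratio threshold in (0, 1].
#' @return Data frame with columns `idx_a`, `idx_b` (1-based keypoint
#'   indices) and `dist` (descriptor L2 distance).
#' @export
match_pair <- function(a, b, ratio = 0.8) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  empty <- data.frame(idx_a = integer(0), idx_b = integer(0),
                      dist = numeric(0))
  if (nrow(a$keypoints) == 0 || nrow(b$keypoints) == 0) return(empty)
  S <- tcrossprod(a$descriptors, b$descriptors)    # cosine similarity
  # squared L2 distance between unit vectors: 2 - 2 s
  two_best <- function(M) {
    b1 <- max.col(M, ties.method = "first")
    s1 <- M[cbind(seq_len(nrow(M)), b1)]
    M[cbind(seq_len(nrow(M)), b1)] <- -Inf
    s2 <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
    list(idx = b1, d1 = sqrt(pmax(2 - 2 * s1, 0)),
         d2 = sqrt(pmax(2 - 2 * s2, 0)))
  }
  fwd <- two_best(S)
  rev <- two_best(t(S))
  # mutual nearest neighbours passing the ratio test from both sides,
  # which makes the result symmetric in its arguments
  mutual <- rev$idx[fwd$idx] == seq_len(nrow(S))
  pass <- fwd$d1 < ratio * fwd$d2 &
    rev$d1[fwd$idx] < ratio * rev$d2[fwd$idx]
  keep <- which(pass & mutual)
  data.frame(idx_a = keep, idx_b = fwd$idx[keep], dist = fwd$d1[keep])
}

#' Match all image pairs of a survey
#'
#' Runs [match_pair()] and [filter_epipolar()] over every unordered image
#' pair (all O(N^2) combinations by default, mixing bands freely), with an
#' optional prefilter that skips pairs whose camera positions (if known
#' from a flight plan) are too far apart to overlap.
#'
#' @param features List of feature sets.
#' @param ratio Lowe ratio.
#' @param epi_threshold_px Sampson inlier threshold (pixels).
#' @param seed RANSAC seed.
#' @param min_inliers Pairs with fewer epipolar inliers are dropped.
#' @param positions Optional n x 3 matrix of approximate camera positions
#'   for the proximity prefilter.
#' @param max_pair_dist_m Prefilter distance (used only with `positions`).
#' @param verbose Print per-pair progress.
#' @return List of pairwise match records (class `"pair_matches"`), plus a
#'   `summary` attribute: data frame of pairs, candidates and inliers.
#' @export
match_all_pairs <- function(features, ratio = 0.8, epi_threshold_px = 2,
                            seed = 1, min_inliers = 16, positions = NULL,
                            max_pair_dist_m = Inf, verbose = FALSE) {
  n <- length(features)
  out <- list()
  summ <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.null(positions) &&
          sqrt(sum((positions[i, ] - positions[j, ])^2)) > max_pair_dist_m)
        next
      cand <- match_pair(features[[i]], features[[j]], ratio)
      if (nrow(cand) < max(min_inliers, 8)) {
        # cannot reach the inlier floor: record and skip the RANSAC cost
        summ <- rbind(summ, data.frame(img_a = i, img_b = j,
                                       n_candidates = nrow(cand),
                                       n_inliers = 0L))
        next
      }
      pm <- filter_epipolar(cand, features[[i]], features[[j]],
                            threshold_px = epi_threshold_px,
                            seed = seed + 1000L * i + j)
      pm$img_a <- i; pm$img_b <- j
      n_in <- sum(pm$inlier)
      summ <- rbind(summ, data.frame(img_a = i, img_b = j,
                                     n_candidates = nrow(cand),
                                     n_inliers = n_in))
      if (verbose) message(sprintf("pair %d-%d: %d cand, %d inliers",
                                   i, j, nrow(cand), n_in))
      if (pm$status == "matched" && n_in >= min_inliers)
        out[[length(out) + 1]] <- pm
    }
  }
  attr(out, "summary") <- summ
  out
}

#' Match statistics by band combination
#'
#' Summarises matched pairs the way survey reports do: pair counts and the
#' mean number of inlier feature matches per pair, split by band
#' combination (colour-colour, colour-NIR, NIR-NIR).
#'
#' @param matches Result of [match_all_pairs()].
#' @param bands Character vector: band label (`"colour"` or `"nir"`) per
#'   image id.
#' @return Data frame with columns `combination`, `n_pairs`,
#'   `mean_matches_per_pair`.
#' @export
match_statistics <- function(matches, bands) {
  combos <- vapply(matches, function(m) {
    b <- sort(c(bands[m$img_a], bands[m$img_b]))
    paste(b, collapse = "-")
  }, "")
  n_in <- vapply(matches, function(m) sum(m$inlier), 0)
  levels <- c("colour-colour", "colour-nir", "nir-nir")
  do.call(rbind, lapply(levels, function(l) {
    sel <- combos == l
    data.frame(combination = l, n_pairs = sum(sel),
               mean_matches_per_pair = if (any(sel)) mean(n_in[sel]) else 0)
  }))
}
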