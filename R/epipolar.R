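#' Normalised eight-point fundamental matrix estimate
#'
#' Hartley-normalised linear estimate of the fundamental matrix from >= 8
#' correspondences, with the rank-2 constraint enforced by truncating the
#' smallest singular value.
#'
#' @param pa,pb n x 2 matrices of corresponding pixel coordinates.
#' @return 3x3 fundamental matrix `F` (up to scale) with
#'   `pb' F pa = 0`; unit Frobenius norm.
#' @export
eight_point <- function(pa, pb) {
  stopifnot(nrow(pa) >= 8, nrow(pa) == nrow(pb))
  na <- normalise_points(pa); nb <- normalise_points(pb)
  a <- na$pts; b <- nb$pts
  A <- cbind(b[, 1] * a[, 1], b[, 1] * a[, 2], b[, 1],
             b[, 2] * a[, 1], b[, 2] * a[, 2], b[, 2],
             a[, 1], a[, 2], 1)
  f <- svd(A, nu = 0, nv = 9)$v[, 9]
  F0 <- matrix(f, 3, 3, byrow = TRUE)
  s <- svd(F0)
  F0 <- s$u %*% diag(c(s$d[1:2], 0)) %*% t(s$v)
  F0 <- t(nb$T) %*% F0 %*% na$T
  F0 / sqrt(sum(F0^2))
}

normalise_points <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  list(pts = cbind((p[, 1] - ctr[1]) * s, (p[, 2] - ctr[2]) * s), T = T)
}

#' Sampson distance of correspondences to a fundamental matrix
#'
#' First-order geometric distance of each correspondence to the epipolar
#' constraint `pb' F pa = 0`, in pixels.
#'
#' @param F 3x3 fundamental matrix.
#' @param pa,pb n x 2 corresponding pixel coordinates.
#' @return Numeric vector of Sampson distances.
#' @export
sampson_distance <- function(F, pa, pb) {
  ha <- cbind(pa, 1); hb <- cbind(pb, 1)
  Fa <- ha %*% t(F)     # rows: F %*% a
  Fb <- hb %*% F        # rows: t(F) %*% b
  num <- rowSums(hb * Fa)^2
  den <- Fa[, 1]^2 + Fa[, 2]^2 + Fb[, 1]^2 + Fb[, 2]^2
  sqrt(num / pmax(den, 1e-300))
}

#' Epipolar outlier rejection with RANSAC
#'
#' Robustly fits a fundamental matrix to candidate correspondences with
#' RANSAC over the normalised eight-point estimate, marks inliers by
#' Sampson distance and re-estimates F on all inliers.  The iteration
#' count adapts to the observed inlier ratio at 99.9% confidence.
#' Deterministic for a fixed seed.
#'
#' @param candidates Data frame from [match_pair()] (`idx_a`, `idx_b`).
#' @param a,b The corresponding [extract_features()] sets.
#' @param threshold_px Sampson inlier threshold in pixels.
#' @param seed RANSAC seed.
#' @param max_iter Iteration cap.
#' @param confidence RANSAC confidence level.
#' @return List of class `"pair_matches"`: `status` (`"matched"` or
#'   `"unmatched"`), `idx_a`, `idx_b`, `inlier` (logical), `F` (3x3 rank-2,
#'   unit norm, or NULL), `img_a`, `img_b`.
#' @export
filter_epipolar <- function(candidates, a, b, threshold_px = 2, seed = 1,
                            max_iter = 600, confidence = 0.999) {
  unmatched <- structure(list(status = "unmatched",
                              idx_a = candidates$idx_a,
                              idx_b = candidates$idx_b,
                              inlier = rep(FALSE, nrow(candidates)),
                              F = NULL), class = "pair_matches")
  n <- nrow(candidates)
  if (n < 8) return(unmatched)
  pa <- a$keypoints[candidates$idx_a, , drop = FALSE]
  pb <- b$keypoints[candidates$idx_b, , drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best_in <- logical(n); best_cnt <- 0
  it <- 0; n_iter <- max_iter
  while (it < n_iter) {
    it <- it + 1
    s <- sample.int(n, 8)
    Fi <- tryCatch(eight_point(pa[s, ], pb[s, ]), error = function(e) NULL)
    if (is.null(Fi)) next
    d <- sampson_distance(Fi, pa, pb)
    inl <- d < threshold_px
    cnt <- sum(inl)
    if (cnt > best_cnt) {
      best_cnt <- cnt; best_in <- inl
      ratio <- max(cnt / n, 1e-6)
      n_iter <- min(max_iter,
                    ceiling(log(1 - confidence) / log(1 - min(ratio^8, 1 - 1e-12))))
    }
  }
  if (best_cnt < 8) return(unmatched)
  Ff <- eight_point(pa[best_in, , drop = FALSE], pb[best_in, , drop = FALSE])
  d <- sampson_distance(Ff, pa, pb)
  inl <- d < threshold_px
  if (sum(inl) < 8) return(unmatched)
  structure(list(status = "matched", idx_a = candidates$idx_a,
                 idx_b = candidates$idx_b, inlier = inl, F = Ff,
                 sampson = d), class = "pair_matches")
}
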