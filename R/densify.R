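#' Densify a reconstruction by patch correlation
#'
#' Produces a dense pointcloud from a registered model: every registered
#' image in turn acts as reference; on a regular `cell_px` pixel grid, the
#' depth along each pixel ray is found by zero-mean normalised
#' cross-correlation (ZNCC) search along the epipolar line in a partner
#' view of the same band, refined to subpixel, and triangulated.  Points
#' must pass a correlation threshold and a peak-uniqueness test.  The
#' partner is the same-band view sharing the most tracks among those with
#' a baseline-to-depth ratio in a usable stereo range; images with no such
#' partner are skipped.
#'
#' @param model Registered `"recon_model"`.
#' @param images List of image arrays (by image id).
#' @param cell_px Sampling grid pitch in pixels (5 targets roughly one
#'   point per 5x5 patch).
#' @param half Correlation patch half-width (patch is `2*half+1` squared).
#' @param zncc_min Minimum acceptable correlation.
#' @param baseline_range Usable baseline/median-depth ratio range.
#' @param bands Optional band label per image id (stored per point).
#' @param verbose Print progress.
#' @return The model with `dense` (n x 3 matrix), `dense_band` (character),
#'   `dense_src` (reference image id) filled in.
#' @export
densify <- function(model, images, cell_px = 5, half = 3, zncc_min = 0.8,
                    baseline_range = c(0.04, 0.6), bands = NULL,
                    verbose = FALSE) {
  reg <- registered_ids(model)
  if (length(reg) < 2) stop("densification needs a registered model")
  valid <- which(!is.na(model$points[, 1]))
  pts_by_img <- split(model$obs$track, model$obs$img)
  dense <- list(); dband <- list(); dsrc <- list()
  for (i in reg) {
    tr_i <- intersect(pts_by_img[[as.character(i)]], valid)
    if (length(tr_i) < 10) next
    pose_i <- model$poses[[i]]
    depths <- (model$points[tr_i, , drop = FALSE] -
                 matrix(pose_i$centre, length(tr_i), 3, byrow = TRUE)) %*% pose_i$R[3, ]
    depths <- depths[depths > 0]
    if (length(depths) < 10) next
    med_d <- stats::median(depths)
    dmin <- max(stats::quantile(depths, 0.02) * 0.8, med_d * 0.3)
    dmax <- stats::quantile(depths, 0.98) * 1.25
    # partner: same band, usable baseline, most shared tracks
    cand <- setdiff(reg, i)
    if (!is.null(bands)) cand <- cand[bands[cand] == bands[i]]
    score <- vapply(cand, function(j) {
      b <- sqrt(sum((model$poses[[j]]$centre - pose_i$centre)^2)) / med_d
      if (b < baseline_range[1] || b > baseline_range[2]) return(-1)
      length(intersect(pts_by_img[[as.character(j)]], tr_i))
    }, 0)
    if (all(score < 0)) next
    j <- cand[which.max(score)]
    ii <- model$intr[[model$body[i]]]
    ij <- model$intr[[model$body[j]]]
    dp <- densify_pair_cpp(
      luminance(images[[i]]), luminance(images[[j]]),
      model$poses[[i]]$R, pose_i$centre,
      c(ii$focal, ii$cx, ii$cy, ii$k1, ii$k2),
      model$poses[[j]]$R, model$poses[[j]]$centre,
      c(ij$focal, ij$cx, ij$cy, ij$k1, ij$k2),
      as.integer(cell_px), as.integer(half), zncc_min, dmin, dmax)
    if (nrow(dp$X) == 0) next
    dense[[length(dense) + 1]] <- dp$X
    dband[[length(dband) + 1]] <- rep(if (is.null(bands)) NA_character_
                                      else bands[i], nrow(dp$X))
    dsrc[[length(dsrc) + 1]] <- rep(i, nrow(dp$X))
    if (verbose)
      message(sprintf("densify ref %d (partner %d): %d points", i, j, nrow(dp$X)))
  }
  model$dense <- do.call(rbind, dense)
  model$dense_band <- unlist(dband)
  model$dense_src <- unlist(dsrc)
  model
}
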