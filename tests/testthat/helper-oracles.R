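# Independent oracles used by the tests.  These deliberately re-derive
# results by brute force or direct formula evaluation, separate from the
# package's implementation paths.

# direct pinhole + radial distortion projection, written out longhand
oracle_project <- function(X, R, C, f, cx, cy, k1, k2) {
  Xc <- R %*% (X - C)
  x <- Xc[1] / Xc[3]
  y <- Xc[2] / Xc[3]
  r2 <- x * x + y * y
  d <- 1 + k1 * r2 + k2 * r2 * r2
  c(f * x * d + cx, f * y * d + cy)
}

# least-squares alignment residual by dense rotation sampling plus local
# Nelder-Mead refinement (scale fixed at 1)
oracle_align_residual <- function(source, target, n_samples = 4000,
                                  seed = 1) {
  set.seed(seed)
  sc <- colMeans(source); tc <- colMeans(target)
  S <- sweep(source, 2, sc); Tm <- sweep(target, 2, tc)
  resid_for <- function(R) {
    tr <- tc - as.numeric(R %*% sc)
    sum((t(R %*% t(source)) + matrix(tr, nrow(source), 3, byrow = TRUE) -
           target)^2)
  }
  rand_rot <- function() {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
           3, 3, byrow = TRUE)
  }
  best <- Inf; best_w <- c(0, 0, 0)
  for (i in seq_len(n_samples)) {
    R <- rand_rot()
    r <- resid_for(R)
    if (r < best) { best <- r; best_R <- R }
  }
  # refine over axis-angle around the best sample
  f_opt <- function(w) resid_for(shoremapper::rodrigues(w) %*% best_R)
  o <- stats::optim(c(0, 0, 0), f_opt, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 4000))
  sqrt(o$value / nrow(source))  # RMS residual, metres
}

# brute-force best-4 view selection for every face: all-pairs distances,
# visibility given, sort with image-id tie-break
oracle_best4 <- function(face_centres, cam_centres, visible, cam_ids) {
  t(vapply(seq_len(nrow(face_centres)), function(f) {
    d <- sqrt(colSums((t(cam_centres) - face_centres[f, ])^2))
    vis <- which(visible[f, ])
    ord <- vis[order(d[vis], cam_ids[vis])]
    out <- rep(0L, 4)
    out[seq_len(min(4, length(ord)))] <- cam_ids[ord[seq_len(min(4, length(ord)))]]
    out
  }, integer(4)))
}

# fundamental matrix from two camera matrices (independent construction)
oracle_fundamental <- function(R1, C1, R2, C2, K) {
  # relative pose: x2 = R_rel x1 + t_rel in camera frames
  R_rel <- R2 %*% t(R1)
  t_rel <- -R_rel %*% (R1 %*% (C2 - C1))
  E <- matrix(c(0, t_rel[3], -t_rel[2],
                -t_rel[3], 0, t_rel[1],
                t_rel[2], -t_rel[1], 0), 3, 3, byrow = TRUE) %*% R_rel
  Fm <- t(solve(K)) %*% E %*% solve(K)
  Fm / sqrt(sum(Fm^2))
}

frob_dist_f <- function(F1, F2) {
  F1 <- F1 / sqrt(sum(F1^2)); F2 <- F2 / sqrt(sum(F2^2))
  min(sqrt(sum((F1 - F2)^2)), sqrt(sum((F1 + F2)^2)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}
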