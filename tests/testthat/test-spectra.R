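test_that("band response is a trapezoidal spectrum x response integral", {
  resp <- gaussian_response(606, 30, "red")
  flat <- spectrum(c(400, 800), c(0.5, 0.5))
  v <- predict_band_response(flat, resp)$value
  expect_equal(v, 0.5 * response_integral(resp), tolerance = 1e-9)
  zero <- spectrum(c(400, 800), c(0, 0))
  expect_equal(predict_band_response(zero, resp)$value, 0)
})

test_that("band response is linear in the spectrum", {
  set.seed(1)
  g <- seq(400, 800, 5)
  resp <- gaussian_response(530, 40, "green")
  s1 <- spectrum(g, runif(length(g), 0, 0.5))
  s2 <- spectrum(g, runif(length(g), 0, 0.5))
  a <- 0.3; b <- 0.6
  mix <- spectrum(g, a * s1$reflectance + b * s2$reflectance)
  expect_equal(predict_band_response(mix, resp)$value,
               a * predict_band_response(s1, resp)$value +
                 b * predict_band_response(s2, resp)$value,
               tolerance = 1e-9)
})

test_that("disjoint wavelength supports are rejected", {
  resp <- spectral_response(seq(700, 800, 5), rep(1, 21), "nir")
  s <- spectrum(seq(400, 500, 5), rep(0.5, 21))
  expect_error(predict_band_response(s, resp), "disjoint")
})

test_that("response estimation recovers a known Gaussian curve", {
  set.seed(42)
  g <- seq(400, 800, 5)
  truth <- gaussian_response(606, 30, "red", g)
  # 24 random smooth panel spectra (Gaussian mixtures)
  panels <- lapply(1:24, function(i) {
    r <- rep(0.05, length(g))
    for (k in 1:4)
      r <- r + runif(1, 0, 0.3) *
        exp(-0.5 * ((g - runif(1, 380, 820)) / runif(1, 30, 120))^2)
    spectrum(g, pmin(r, 1))
  })
  vals <- vapply(panels, function(sp)
    predict_band_response(sp, truth)$value, 0)
  est <- estimate_response(panels, cbind(vals), channels = "red",
                           smoothness_weight = 1e-4)
  expect_lt(abs(peak_wavelength(est$red) - 606), 10)
  # curve RMSE below 1% of peak on a noiseless well-conditioned design
  err <- est$red$sensitivity - truth$sensitivity
  expect_lt(sqrt(mean(err^2)), 0.01 * max(truth$sensitivity))
})

test_that("flat (rank-deficient) panel sets are rejected", {
  g <- seq(400, 800, 5)
  panels <- lapply(seq(0.1, 0.9, length.out = 10), function(a)
    spectrum(g, rep(a, length(g))))
  vals <- vapply(panels, function(sp) 0.5 * sp$reflectance[1], 0)
  expect_error(estimate_response(panels, cbind(vals), channels = "red"),
               "rank-deficient")
})

test_that("large smoothness weight drives the curve towards constant", {
  set.seed(3)
  g <- seq(400, 800, 5)
  truth <- gaussian_response(606, 30, "red", g)
  panels <- lapply(1:24, function(i) {
    r <- rep(0.05, length(g))
    for (k in 1:4)
      r <- r + runif(1, 0, 0.3) *
        exp(-0.5 * ((g - runif(1, 380, 820)) / runif(1, 30, 120))^2)
    spectrum(g, pmin(r, 1))
  })
  vals <- vapply(panels, function(sp)
    predict_band_response(sp, truth)$value, 0)
  est <- estimate_response(panels, cbind(vals), channels = "red",
                           smoothness_weight = 1e6)
  s <- est$red$sensitivity
  expect_lt(stats::sd(s) / max(mean(s), 1e-12), 0.05)
})

test_that("predicted NDVI behaves at its defining limits", {
  red <- gaussian_response(606, 35, "red")
  nir <- gaussian_response(740, 30, "nir")
  # flat spectrum with gains that white-balance a flat surface -> 0
  flat <- spectrum(c(350, 850), c(0.99, 0.99))
  w <- c(red = predict_band_response(flat, red)$value,
         nir = predict_band_response(flat, nir)$value)
  gains <- white_balance_gains(w)
  half <- spectrum(c(350, 850), c(0.5, 0.5))
  expect_equal(predict_ndvi(half, red, nir, gains), 0, tolerance = 1e-9)
  # reflectance confined to the red channel's support -> -1 (up to the
  # vanishing tail overlap of the NIR channel below 600 nm)
  g <- seq(400, 800, 5)
  red_only <- spectrum(g, ifelse(g < 600, 0.5, 0))
  expect_equal(predict_ndvi(red_only, red, nir), -1, tolerance = 1e-3)
  # algae-like red edge beats flat rock
  algae <- spectrum(g, 0.05 + 0.45 / (1 + exp(-(g - 700) / 12)))
  rock <- spectrum(g, rep(0.3, length(g)))
  expect_gt(predict_ndvi(algae, red, nir, gains),
            predict_ndvi(rock, red, nir, gains))
  # invariant to common positive scaling of the gains
  expect_equal(predict_ndvi(algae, red, nir, gains),
               predict_ndvi(algae, red, nir, gains * 7.3), tolerance = 1e-12)
  expect_error(predict_ndvi(spectrum(g, rep(0, length(g))), red, nir),
               "undefined")
})

test_that("spectra round-trip through CSV", {
  g <- seq(400, 800, 10)
  s <- spectrum(g, runif(length(g)))
  p <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, p)
  s2 <- read_spectrum_csv(p)
  expect_equal(s2$reflectance, s$reflectance, tolerance = 1e-12)
  unlink(p)
})
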