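# Astigmatic CTF model, tilted micrograph synthesis, corrected power
# spectra and defocus fitting. Module tests use a reduced field (n = 256,
# 64 px tiles) to stay fast; the full 512 px Monte-Carlo lives in the
# acceptance suite.

p_truth <- ctf_params(16000, 14000, 30, pixel_size = 4)
p_start <- ctf_params(15000, pixel_size = 4)
srch <- list(min = 8000, max = 25000, step = 500)
band <- c(1 / 40, 1 / 10)

test_that("ctf_2d anchors: origin value, astigmatism-free isotropy", {
  expect_equal(ctf_2d(0, 0, p_truth), -0.07)
  iso <- ctf_params(15000, 15000, 45, pixel_size = 2)
  phis <- seq(0, 2 * pi, length.out = 13)
  v <- ctf_2d(0.05 * cos(phis), 0.05 * sin(phis), iso)
  expect_lt(diff(range(v)), 1e-12)
})

test_that("ctf_2d is even and invariant under the astigmatism swap", {
  set.seed(1)
  fx <- runif(50, -0.1, 0.1); fy <- runif(50, -0.1, 0.1)
  expect_equal(ctf_2d(fx, fy, p_truth), ctf_2d(-fx, -fy, p_truth))
  swapped <- ctf_params(14000, 16000, 120, pixel_size = 4)  # canonicalized
  expect_equal(swapped$defocus1, 16000)
  expect_equal(swapped$astig_angle, 30)
  expect_equal(ctf_2d(fx, fy, p_truth), ctf_2d(fx, fy, swapped))
})

test_that("first zero matches a 1D bisection oracle", {
  p <- ctf_params(10000, 10000, 0, voltage = 300, cs = 2.7,
                  amplitude_contrast = 0.07, pixel_size = 1)
  # oracle: bisect the radial CTF for its first sign change
  f <- seq(1e-4, 0.2, by = 1e-4)
  v <- ctf_2d(f, 0, p)
  i <- which(diff(sign(v)) != 0)[1]
  oracle_zero <- uniroot(function(x) ctf_2d(x, 0, p), c(f[i], f[i + 1]),
                         tol = 1e-10)$root
  # analytic check: chi + asin(w) = pi at the first zero (underfocus branch)
  lambda <- 12.2639 / sqrt(300e3 + 0.97845e-6 * 300e3^2)
  chi <- function(x) pi * lambda * 1e4 * x^2 - 0.5 * pi * 2.7e7 * lambda^3 * x^4
  expect_equal(chi(oracle_zero) + asin(0.07), pi, tolerance = 1e-6)
})

test_that("synthetic micrographs are seeded and carry the stated gradient", {
  g <- tilt_geometry(0, 51)
  a <- synth_tilted_micrograph(p_truth, g, dose = 3, seed = 3, n = 256)
  b <- synth_tilted_micrograph(p_truth, g, dose = 3, seed = 3, n = 256)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  # plane-geometry oracle: slope of the height term per pixel
  h <- bisectr:::tilt_height_A(1, 0, tilt_geometry(90, 51), 4)
  expect_equal(h, -4 * tan(51 * pi / 180), tolerance = 1e-9)
  h2 <- bisectr:::tilt_height_A(0, 1, tilt_geometry(0, 51), 4)
  expect_equal(h2, 4 * tan(51 * pi / 180), tolerance = 1e-9)
  expect_error(synth_tilted_micrograph(p_truth, g, n = 64), ">= 256")
})

test_that("zero-tilt corrected spectrum equals plain tiled averaging", {
  g0 <- tilt_geometry(0, 0)
  img <- synth_tilted_micrograph(p_truth, g0, dose = 3, seed = 5, n = 256)
  s1 <- tilted_power_spectrum(img, g0, 64, 15000, 4, correct = TRUE)
  s2 <- tilted_power_spectrum(img, g0, 64, 15000, 4, correct = FALSE)
  expect_equal(unclass(s1)[, ], unclass(s2)[, ], tolerance = 1e-12)
})

test_that("background subtraction leaves ~zero-mean shells on pure noise", {
  set.seed(8)
  noise <- matrix(rnorm(256^2), 256)
  sp <- tilted_power_spectrum(noise, tilt_geometry(0, 0), 64, 15000, 4)
  bg <- bisectr:::spectrum_background(sp, 4, band[1], band[2], 4)
  resid <- sp - bg
  sh <- bisectr:::shell_index(dim(sp))
  nsh <- floor(64 / 2)
  prof <- bisectr:::shell_mean(resid, sh, nsh)
  freqs <- (seq_len(nsh) - 1) / (64 * 4)
  sel <- freqs >= band[1] & freqs <= band[2]
  expect_lt(max(abs(prof[sel])) / mean(sp), 0.05)
})

test_that("noiseless model spectrum is fitted to within one grid step", {
  model <- abs(bisectr:::ctf_image(128, ctf_params(15000, pixel_size = 4)))^2
  attr(model, "pixel_size") <- 4
  fit <- fit_astigmatic_ctf(model, srch, p_start, fit_band = band)
  dz_mean <- (fit$params$defocus1 + fit$params$defocus2) / 2
  expect_lt(abs(dz_mean - 15000), srch$step)
  # |CTF| model against a |CTF|^2 input: high but not unit correlation
  expect_gt(fit$fit_score, 0.8)
})

test_that("astigmatic recovery works on a reduced zero-tilt fixture", {
  g0 <- tilt_geometry(0, 0)
  img <- synth_tilted_micrograph(p_truth, g0, dose = 3, seed = 6, n = 384)
  hint <- estimate_center_defocus(img, g0, p_start, srch, tile_size = 128,
                                  pixel_size = 4, fit_band = band)
  expect_lt(abs(hint - 15000), 2 * srch$step)
  sp <- tilted_power_spectrum(img, g0, 128, hint, 4)
  fit <- fit_astigmatic_ctf(sp, srch, p_start, fit_band = band)
  expect_lt(abs(fit$params$defocus1 - 16000), 500)
  expect_lt(abs(fit$params$defocus2 - 14000), 500)
  dang <- abs(((fit$params$astig_angle - 30 + 90) %% 180) - 90)
  expect_lt(dang, 10)
})

test_that("tilt correction sharpens rings and repeats across seeds", {
  g <- tilt_geometry(0, 51)
  img <- synth_tilted_micrograph(p_truth, g, dose = 3, seed = 7, n = 512)
  hint <- estimate_center_defocus(img, g, p_start, srch, pixel_size = 4,
                                  fit_band = band)
  spc <- tilted_power_spectrum(img, g, 128, hint, 4, correct = TRUE)
  spu <- tilted_power_spectrum(img, g, 128, hint, 4, correct = FALSE)
  expect_gt(ring_contrast(spc, 4, band), ring_contrast(spu, 4, band))
  # repeatability: spectra from two seeds correlate beyond the first zero
  img2 <- synth_tilted_micrograph(p_truth, g, dose = 3, seed = 17, n = 512)
  spc2 <- tilted_power_spectrum(img2, g, 128, hint, 4, correct = TRUE)
  # per-pixel periodograms carry exponential noise; the ring structure is
  # the reproducible part, so compare radial profiles beyond the ~17 A
  # first zero
  r1 <- radial_average(spc, 4); r2 <- radial_average(spc2, 4)
  sel <- r1$freq >= 1 / 17 & r1$freq <= band[2] & !is.na(r1$value)
  expect_gt(cor(r1$value[sel], r2$value[sel]), 0.9)
})

test_that("degenerate search ranges and bad geometry are rejected", {
  model <- abs(bisectr:::ctf_image(64, p_start))^2
  attr(model, "pixel_size") <- 4
  expect_error(fit_astigmatic_ctf(model, list(min = 2, max = 1), p_start),
               "degenerate")
  expect_error(tilt_geometry(0, 95), "< 90")
})
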