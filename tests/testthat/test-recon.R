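# Defocus assignment, extraction, scoring, exposure weights, Fourier
# reconstruction and FSC.

test_that("per-particle defocus offsets follow the rotation geometry", {
  geoms <- lapply(c(0, 36, -36), function(th) tilt_geometry(0, th))
  ctfs <- lapply(1:3, function(i) ctf_params(20000, pixel_size = 3))
  origin <- list(x_um = 0, y_um = 0, z_um = 0)
  d0 <- assign_particle_defocus(origin, geoms, ctfs)
  expect_equal(d0$defocus1, rep(20000, 3))
  p <- list(x_um = 0.1, y_um = 0.5, z_um = 0.2)
  d <- assign_particle_defocus(p, geoms, ctfs)
  # oracle: z' = -y sin(theta) + z cos(theta), in Angstrom
  expect_equal(d$defocus_offset_A[2],
               (-0.5 * sin(36 * pi / 180) + 0.2 * cos(36 * pi / 180)) * 1e4,
               tolerance = 1e-6)
  expect_equal(d$defocus_offset_A[2], -1320.89, tolerance = 0.01)
  expect_equal(d$defocus1, 20000 + d$defocus_offset_A)
  # mirror particles in y get opposite offsets at z = 0
  m1 <- assign_particle_defocus(list(x_um = 0, y_um = 0.4, z_um = 0), geoms, ctfs)
  m2 <- assign_particle_defocus(list(x_um = 0, y_um = -0.4, z_um = 0), geoms, ctfs)
  expect_equal(m1$defocus_offset_A, -m2$defocus_offset_A)
  # linearity in position and d(offset)/d(theta) at 0 equals -y (per radian)
  eps <- 1e-4
  gp <- lapply(c(eps, -eps), function(th) tilt_geometry(0, th))
  dd <- assign_particle_defocus(p, gp, ctfs[1:2])
  deriv <- (dd$defocus_offset_A[1] - dd$defocus_offset_A[2]) /
    (2 * eps * pi / 180)
  expect_equal(deriv, -0.5 * 1e4, tolerance = 1)
  expect_error(assign_particle_defocus(p, geoms, ctfs[1:2]), "one CTF per tilt")
})

test_that("extraction centres boxes on point sources at every tilt", {
  scheme <- scheme_fixture("pm36")
  angles <- scheme$angles
  geoms <- lapply(angles, function(th) tilt_geometry(0, th))
  n_img <- 128; px <- 3
  parts <- data.frame(particle_id = 1:2,
                      x_um = c(0.006, -0.008), y_um = c(0.009, -0.005),
                      z_um = c(0.004, -0.006),
                      e1_deg = 0, e2_deg = 0, e3_deg = 0)
  imgs <- lapply(angles, function(th) {
    img <- matrix(0, n_img, n_img)
    for (j in 1:2) {
      ctr <- bisectr:::project_center_px(
        c(parts$x_um[j], parts$y_um[j], parts$z_um[j]),
        tilt_geometry(0, th), px, n_img)
      img[round(ctr[1]), round(ctr[2])] <- 1   # point source
    }
    img
  })
  ex <- extract_particle_projections(imgs, geoms, parts, box = 16,
                                     pixel_size = px)
  expect_equal(nrow(ex$meta), 2 * length(angles))
  for (i in seq_len(dim(ex$stack)[3])) {
    pk <- which(ex$stack[, , i] == 1, arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(9, 9))    # box/2 + 1: centred
  }
  # near-edge particle: invisible at low tilt (where y-apparent is largest),
  # visible at high tilt after foreshortening; rows simply absent
  far <- data.frame(particle_id = 3, x_um = 0, y_um = 0.018, z_um = 0,
                    e1_deg = 0, e2_deg = 0, e3_deg = 0)
  ex2 <- extract_particle_projections(imgs, geoms, far, box = 16,
                                      pixel_size = px)
  expect_lt(nrow(ex2$meta), length(angles))
  # fully invisible particle errors out (single particle -> empty stack)
  gone <- data.frame(particle_id = 4, x_um = 0.5, y_um = 0, z_um = 0,
                     e1_deg = 0, e2_deg = 0, e3_deg = 0)
  expect_warning(expect_error(
    extract_particle_projections(imgs, geoms, gone, 16, px), "no projections"),
    "visible in no tilt")
})

test_that("scores are 1 for self, |.|-symmetric, and match the null oracle", {
  sim <- tiny_particle_sim(n_particles = 2, seed = 31)
  meta <- sim$meta
  # rebuild noiseless reprojections as 'data': score ~ 1
  ref <- bisectr:::ref_transform(sim$phantom)
  stack <- sim$stack
  sc <- score_projections(stack, sim$phantom, meta, band = c(20, 8),
                          pixel_size = 3)
  expect_true(all(sc > 0.95))
  # contrast inversion leaves the score unchanged
  sc_inv <- score_projections(-stack, sim$phantom, meta, band = c(20, 8),
                              pixel_size = 3)
  expect_equal(sc, sc_inv, tolerance = 1e-12)
  # pure-noise projections: |CC| null level matches a resampling oracle
  set.seed(77)
  nnoise <- 40
  noise_stack <- array(rnorm(32 * 32 * nnoise), c(32, 32, nnoise))
  nmeta <- do.call(rbind, lapply(seq_len(nnoise), function(i) {
    r <- meta[1 + (i %% nrow(meta)), ]
    r
  }))
  sc_null <- score_projections(noise_stack, sim$phantom, nmeta,
                               band = c(20, 8), pixel_size = 3)
  n_band <- length(bisectr:::band_mask(32, 3, c(20, 8)))
  # folded-normal mean of |CC| over ~n_band/2 independent complex samples
  oracle <- replicate(400, {
    z <- complex(real = rnorm(n_band / 2), imaginary = rnorm(n_band / 2))
    w <- complex(real = rnorm(n_band / 2), imaginary = rnorm(n_band / 2))
    Mod(sum(z * Conj(w))) / sqrt(sum(Mod(z)^2) * sum(Mod(w)^2))
  })
  expect_lt(abs(mean(sc_null) - mean(oracle)), 3 * sd(oracle) / sqrt(nnoise) + 0.02)
  expect_error(score_projections(stack, sim$phantom, meta, band = c(8, 20),
                                 pixel_size = 3), "band")
})

test_that("exposure weights: anchors, bounds and monotone response", {
  # equal scores: every B = 0, weights identically 1
  w <- derive_exposure_weights(rep(0.5, 10), rep(1:5, 2))
  expect_true(all(w$B_A2 == 0))
  # decreasing scores: B increases in acquisition order; w never amplifies
  s <- seq(0.4, 0.1, length.out = 8)
  w2 <- derive_exposure_weights(s, 1:8, c_A2 = 100)
  expect_true(all(diff(w2$B_A2) > 0))
  expect_equal(min(w2$B_A2), 0)
  f <- seq(0, 0.2, by = 0.01)
  for (B in w2$B_A2) {
    wf <- exp(-B * f^2 / 4)
    expect_equal(wf[1], 1)
    expect_true(all(wf > 0 & wf <= 1))
  }
  # log mode reproduces the amplitude-ratio inversion
  w3 <- derive_exposure_weights(c(0.4, 0.2), c(1, 2), c_A2 = "log",
                                band = c(20, 8))
  f0 <- mean(1 / c(20, 8))
  expect_equal(w3$B_A2[2], 4 / f0^2 * log(2), tolerance = 1e-9)
  # contribution surface: rows sum to 1 per frequency, late tilts fade
  contrib <- spectral_contribution(w2, f[-1])
  expect_equal(colSums(contrib), rep(1, length(f) - 1))
  expect_lt(contrib[8, length(f) - 1], contrib[8, 1])
})

test_that("insertion oracle: noiseless particle reconstructs the phantom", {
  box <- 32; px <- 3
  ph <- make_phantom(box, px)
  ph_ref <- bisectr:::ref_transform(ph)
  angles <- generate_grouped_dose_symmetric(88, 2, 1)$angles
  meta <- do.call(rbind, lapply(seq_along(angles), function(ti) data.frame(
    particle_id = 1, tilt_index = ti, theta = angles[ti], axis_angle = 0,
    e1_deg = 25, e2_deg = 40, e3_deg = -15, dx_px = 0.3, dy_px = -0.2,
    defocus1 = 0, defocus2 = 0, astig_angle = 0)))
  ctf_flat <- bisectr:::ctf_image(box, ctf_params(0, pixel_size = px))
  stack <- array(0, c(box, box, nrow(meta)))
  for (i in seq_len(nrow(meta))) {
    R <- bisectr:::proj_rotation(meta[i, ])
    sl <- bisectr:::extract_slice(ph_ref, R) * ctf_flat *
      bisectr:::phase_ramp(box, meta$dx_px[i], meta$dy_px[i])
    stack[, , i] <- bisectr:::slice_to_image(sl)
  }
  rec <- weighted_reconstruct(stack, meta, pixel_size = px,
                              wiener_frac = 0.001)
  mask <- soft_sphere(box, 14)
  cc <- bandlimited_cor(rec$map * mask, ph * mask, 0.25)
  expect_gt(cc, 0.99)
  expect_error(weighted_reconstruct(stack[, , 0, drop = FALSE], meta[0, ], px),
               "empty")
})

test_that("all-equal weights reproduce the unweighted path exactly", {
  sim <- tiny_particle_sim(n_particles = 2, noise_sd = 0.5, seed = 33)
  w0 <- derive_exposure_weights(rep(0.3, nrow(sim$meta)), sim$meta$tilt_index)
  a <- weighted_reconstruct(sim$stack, sim$meta, 3, weights = w0)
  b <- weighted_reconstruct(sim$stack, sim$meta, 3, weights = NULL)
  expect_identical(a$map, b$map)
})

test_that("FSC anchors: self-correlation, noise null, resolution readout", {
  set.seed(41)
  v <- array(rnorm(24^3), c(24, 24, 24))
  f_self <- compute_fsc(v, v, pixel_size = 2)
  expect_true(all(abs(f_self$fsc - 1) < 1e-9))
  # identical half inputs: FSC identically 1
  sim <- tiny_particle_sim(n_particles = 2, noise_sd = 0.3, seed = 42)
  m1 <- sim$meta; m1$particle_id <- 1       # all odd -> same half
  # noise-map null: per-shell |FSC| within the resampling envelope
  reps <- replicate(30, {
    a <- array(rnorm(24^3), c(24, 24, 24))
    b <- array(rnorm(24^3), c(24, 24, 24))
    compute_fsc(a, b, 2)$fsc
  })
  q95_obs <- apply(abs(reps), 1, stats::quantile, 0.95)
  # oracle: per-shell sample size from the shell populations
  sh <- bisectr:::shell_index(c(24, 24, 24))
  nsh <- floor(24 / 2)
  counts <- tabulate(pmin(sh, nsh), nsh)
  oracle_q95 <- vapply(counts, function(n) {
    stats::quantile(abs(replicate(300, {
      x <- rnorm(n); y <- rnorm(n)
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    })), 0.95)
  }, numeric(1))
  expect_lt(max(abs(q95_obs[3:nsh] - oracle_q95[3:nsh])), 0.15)
  # mask argument returns both curves
  msk <- soft_sphere(24, 8)
  fm <- compute_fsc(v, v + array(rnorm(24^3), c(24, 24, 24)), 2, mask = msk)
  expect_false(is.null(fm$masked))
  expect_error(compute_fsc(v * 0, v, 2), "all-zero")
})

test_that("MRC-independent resolution interpolation is linear", {
  freq <- (0:9) / 20
  fsc <- c(1, 1, 1, 0.9, 0.7, 0.5, 0.3, 0.1, 0, 0)
  # crossing of 0.143 between freq 0.30 (fsc 0.3) and 0.35 (fsc 0.1)
  res <- bisectr:::resolution_at(freq, fsc, 0.143)
  f_cross <- 0.30 + (0.3 - 0.143) / (0.3 - 0.1) * 0.05
  expect_equal(res, 1 / f_cross, tolerance = 1e-12)
})
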