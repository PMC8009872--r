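# Grid scene, rendering and the closed-loop acquisition session.

test_that("scenes are deterministic and respect their configuration", {
  s1 <- make_grid_scene(seed = 5)
  s2 <- make_grid_scene(seed = 5)
  expect_identical(s1$rois, s2$rois)
  expect_identical(s1$texture, s2$texture)
  expect_identical(s1$fiducials, s2$fiducials)
  flat <- make_grid_scene(list(topo_sigma_um = 0), seed = 5)
  expect_true(all(flat$rois$z_um == 0))
  # 5x5 lattice at 2.5 um pitch: 25 targets, corner at ~7.07 um
  expect_equal(nrow(s1$rois), 25L)
  expect_equal(max(sqrt(s1$rois$bis_x^2 + s1$rois$bis_y^2)),
               sqrt(2) * 5, tolerance = 1e-9)
})

test_that("rendering is deterministic and foreshortens by cos(theta)", {
  scene <- make_grid_scene(seed = 6)
  set.seed(1)
  stage <- virtual_stage(0, 0)
  stage_tilt(stage, 0)
  set.seed(99); a <- render_view(scene, stage, 30, 128)
  set.seed(99); b <- render_view(scene, stage, 30, 128)
  expect_identical(a, b)
  # projection oracle: separation of two beads perpendicular to the axis
  # halves at 60 degrees
  sc2 <- scene
  sc2$fiducials <- rbind(c(0, -0.08, 0), c(0, 0.08, 0))
  sc2$texture <- sc2$texture * 0
  sep_at <- function(theta) {
    stage$theta <- theta
    img <- render_view(sc2, stage, 30, 128, dose_e_per_A2 = Inf)
    rs <- rowSums(img)                    # beads are dark rows
    (64 + which.min(rs[65:128])) - which.min(rs[1:64])
  }
  expect_equal(sep_at(60), sep_at(0) / 2, tolerance = 0.08)
})

test_that("halving the dose grows shot noise by sqrt(2)", {
  # Poisson statistics oracle: the difference of two renders of the same
  # pose with independent noise draws isolates the shot noise, whose sd
  # scales as 1/sqrt(dose)
  scene <- make_grid_scene(seed = 7)
  stage <- virtual_stage(0, 0)
  noise_sd_at <- function(dose) {
    set.seed(1); a <- render_view(scene, stage, 30, 128, dose_e_per_A2 = dose)
    set.seed(2); b <- render_view(scene, stage, 30, 128, dose_e_per_A2 = dose)
    sd(a - b) / sqrt(2)
  }
  r <- noise_sd_at(0.25) / noise_sd_at(0.5)
  expect_equal(r, sqrt(2), tolerance = 0.1)
})

test_that("a noise-free flat session has ~zero targeting errors", {
  scene <- make_grid_scene(list(topo_sigma_um = 0), seed = 8)
  cfg <- session_config()
  cfg$in_plane_sigma_nm <- 0
  cfg$eucentricity_offset_um <- 0
  cfg$roi_meas_sigma_um <- 0
  cfg$focus_noise_um <- 0
  cfg$outlier_prob <- 0
  log <- run_bisect_session(scene, short_scheme(2), cfg, seed = 8)
  expect_lt(max(abs(log$err_x_um)), 1e-3)
  expect_lt(max(abs(log$err_y_um)), 1e-3)
  expect_lt(max(abs(log$defocus_err_um)), 1e-3)
})

test_that("sessions are deterministic given (scene, config, seed)", {
  scene <- make_grid_scene(seed = 9)
  sch <- short_scheme(2)
  l1 <- run_bisect_session(scene, sch, session_config(), seed = 9)
  l2 <- run_bisect_session(scene, sch, session_config(), seed = 9)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})

test_that("session log structure and defocus bookkeeping are consistent", {
  scene <- make_grid_scene(seed = 10)
  sch <- short_scheme(2)
  log <- run_bisect_session(scene, sch, session_config(FALSE), seed = 10)
  expect_equal(nrow(log), length(sch$angles) * 25)
  expect_equal(unique(log$model), "planar")
  # ground-truth bookkeeping: planar defocus error at tilt theta for a ROI
  # with true offset (y0, z0) is pred_z - (-y0 sin + z0 cos), up to the
  # simulated autofocus noise (same for every ROI within a tilt)
  cfg <- attr(log, "config")
  for (ti in unique(log$tilt_index)) {
    sub <- log[log$tilt_index == ti, ]
    th <- sub$theta[1] * pi / 180
    rois <- scene$rois
    pred_z <- -rois$y_um * sin(th)        # planar model: z0 = 0
    truth <- -rois$y_um * sin(th) + rois$z_um * cos(th)
    resid <- sub$defocus_err_um - (pred_z - truth)
    expect_lt(diff(range(resid)), 1e-9)   # common autofocus term only
    expect_lt(abs(mean(resid)), 4 * cfg$focus_noise_um)
  }
})

test_that("summarize_session matches order-statistics oracles", {
  log <- data.frame(
    tilt_index = rep(1:5, each = 2), theta = rep(c(0, 3, -3, -6, 6), each = 2),
    roi = rep(c("a", "b"), 5),
    err_x_um = 0, err_y_um = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
    defocus_err_um = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  s <- summarize_session(log)
  expect_equal(s$overall$median_err_y_um, 3)
  expect_equal(s$overall$iqr_err_y_um, 2)
  expect_equal(nrow(s$per_tilt), 5)
  zero <- log; zero$err_y_um <- 0; zero$defocus_err_um <- 0
  sz <- summarize_session(zero)
  expect_equal(sz$overall$median_err_y_um, 0)
  expect_equal(sz$overall$iqr_defocus_err_um, 0)
})

test_that("eucentric correction beats the planar model on the same seed", {
  scene <- make_grid_scene(seed = 20)
  sch <- scheme_fixture("pm36")
  on <- summarize_session(run_bisect_session(scene, sch, session_config(TRUE),
                                             seed = 20))$overall
  off <- summarize_session(run_bisect_session(scene, sch, session_config(FALSE),
                                              seed = 20))$overall
  expect_lt(on$median_err_y_um, off$median_err_y_um)
  expect_lt(on$median_defocus_err_um, off$median_defocus_err_um)
})
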