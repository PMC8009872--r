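# Closed-loop multi-target acquisition controller run against the virtual
# stage: two-level tracking, per-ROI eucentric-height modelling, and
# ground-truth error bookkeeping.

#' Default session configuration
#'
#' Two-level tracking thresholds follow the acquisition convention of
#' 100 nm at the coarse level and 5 nm at the target magnification, with the
#' same ~4x magnification ratio between levels; pixel sizes and the 128 px
#' simulated detector are scaled so the fields of view (about 1.0 and 0.26
#' micrometres) match what those thresholds assume. Per-ROI eucentric fits
#' start once five tracked points are available; before that the controller
#' falls back to the planar (z = 0) model.
#'
#' @param correction enable per-ROI eucentric-height correction; with
#'   `FALSE` the planar model is used for the whole series.
#' @export
session_config <- function(correction = TRUE) {
  list(correction = correction,
       bootstrap_points = 5,
       low_mag = list(pixel_size = 160, n = 128, threshold_nm = 100),
       high_mag = list(pixel_size = 30, n = 128, threshold_nm = 5),
       max_iterations = 5,
       tracking_dose_e_per_A2 = 0.5,
       in_plane_sigma_nm = 200,
       eucentricity_offset_um = 0.25,
       roi_meas_sigma_um = 0.005,
       focus_noise_um = 0.01,
       outlier_prob = 0.03,
       outlier_min_tilt = 40,
       outlier_sigma_um = 0.15,
       peak_floor = 0.2,
       drop_outliers = FALSE)
}

#' Run a closed-loop multi-target acquisition session in the simulator
#'
#' For every tilt of `scheme` (acquisition order) the virtual stage is
#' tilted (drawing fresh mechanical jitter), the tracking area is re-centred
#' by two-level iterative tracking against the series' first image, the
#' focus is measured at the tracking area, and every ROI is targeted by
#' beam-image shift using its current geometric model. Each ROI is treated
#' individually and gets its own eucentric-height fit, refined with each
#' additional tilt; points whose simulated correlation peak falls below
#' `peak_floor` are excluded from the fit. Ground-truth targeting and
#' defocus errors are recorded from the simulator state.
#'
#' @param scene a [make_grid_scene()] scene.
#' @param scheme a [tilt_scheme][generate_grouped_dose_symmetric]; first
#'   angle must be 0.
#' @param config list from [session_config()].
#' @param seed integer; seeds all stochastic draws of the session.
#' @param rois data frame of targets (default `scene$rois`).
#' @return `acquisition_log`: data frame with one row per (roi, tilt) in
#'   scheme order (`tilt_index, theta, roi, bis_x_um, bis_y_um, err_x_um,
#'   err_y_um, defocus_err_um, y_obs_um, peak_ok, tracking_iterations,
#'   converged, track_residual_nm, model`), with the per-tilt tracking table
#'   in `attr(, "tracking")` and the effective config in `attr(, "config")`.
#' @export
run_bisect_session <- function(scene, scheme, config = session_config(),
                               seed = 1, rois = scene$rois) {
  cfg <- utils::modifyList(session_config(), config)
  if (!inherits(scheme, "tilt_scheme")) stop_bisectr("expected a tilt_scheme")
  angles <- scheme$angles
  if (angles[1] != 0) stop_bisectr("scheme must start at 0 degrees")
  bis_r <- sqrt(rois$bis_x^2 + rois$bis_y^2)
  if (any(bis_r > 8)) {
    stop_bisectr("ROI beyond the 8 um image-shift radius: %s",
                 rois$id[which.max(bis_r)])
  }
  set.seed(as.integer(seed))
  stage <- virtual_stage(cfg$in_plane_sigma_nm, cfg$eucentricity_offset_um)

  acquire_fn <- function(level) {
    force(level)
    function(delta_nm) {
      apply_image_shift(stage, delta_nm / 1000)
      render_view(scene, stage, pixel_size = level$pixel_size, n = level$n,
                  dose_e_per_A2 = cfg$tracking_dose_e_per_A2)
    }
  }

  # reference images at zero tilt (tilt 1); their residual state is the
  # session's origin: all later errors are relative to what was imaged first.
  # The operator centres the tracking area when selecting targets, so the
  # initial mechanical positioning error is compensated before the
  # references are taken.
  stage_tilt(stage, 0)
  apply_image_shift(stage, -stage$pose_err_um)
  ref_low <- acquire_fn(cfg$low_mag)(c(0, 0))
  ref_high <- acquire_fn(cfg$high_mag)(c(0, 0))
  st_low <- tracking_state(ref_low, "low_mag", cfg$low_mag$pixel_size,
                           cfg$low_mag$threshold_nm, cfg$max_iterations)
  st_high <- tracking_state(ref_high, "high_mag", cfg$high_mag$pixel_size,
                            cfg$high_mag$threshold_nm, cfg$max_iterations)
  ref_shift <- content_shift_um(stage)

  n_roi <- nrow(rois)
  obs <- replicate(n_roi, list(theta = numeric(), y = numeric(),
                               ok = logical()), simplify = FALSE)
  models <- data.frame(y0 = rois$y_um, z0 = 0)  # bootstrapped planar model
  fitted <- rep(FALSE, n_roi)
  log_rows <- vector("list", length(angles) * n_roi)
  track_rows <- vector("list", length(angles))

  for (ti in seq_along(angles)) {
    th <- angles[ti]
    ct <- cos(deg2rad(th)); st_ <- sin(deg2rad(th))
    if (ti == 1) {
      tr <- list(iterations = 1L, converged = TRUE, residual_nm = 0)
    } else {
      stage_tilt(stage, th)
      lo <- iterative_track(acquire_fn(cfg$low_mag), st_low, th)
      hi <- iterative_track(acquire_fn(cfg$high_mag), st_high, th)
      tr <- list(iterations = lo$iterations + hi$iterations,
                 converged = hi$converged, residual_nm = hi$residual_nm)
    }
    # ground-truth residual: displacement of the specimen point that sat at
    # the centre of the reference image. The reference's own baked-in offset
    # foreshortens with cos(theta) perpendicular to the axis, so it enters
    # the comparison scaled by ct.
    resid_um <- content_shift_um(stage) - c(ref_shift[1], ct * ref_shift[2])
    track_rows[[ti]] <- data.frame(
      tilt_index = ti, theta = th,
      iterations = tr$iterations, converged = tr$converged,
      measured_residual_nm = tr$residual_nm,
      true_residual_nm = sqrt(sum(resid_um^2)) * 1000)
    focus_err <- rnorm(1, 0, cfg$focus_noise_um)

    for (ri in seq_len(n_roi)) {
      m <- models[ri, ]
      used_model <- if (fitted[ri]) "eucentric" else "planar"
      pred <- rotate_point_about_tilt_axis(m$y0, m$z0, th)
      y_true <- rois$y_um[ri] * ct + rois$z_um[ri] * st_
      z_true <- -rois$y_um[ri] * st_ + rois$z_um[ri] * ct
      err_x <- -resid_um[1]
      err_y <- pred$y - y_true - resid_um[2]
      defocus_err <- pred$z + focus_err - z_true
      # targeting measurement feeding the next fit update
      is_outlier <- abs(th) >= cfg$outlier_min_tilt &&
        runif(1) < cfg$outlier_prob
      y_obs <- y_true + resid_um[2] +
        rnorm(1, 0, cfg$roi_meas_sigma_um) +
        if (is_outlier) rnorm(1, 0, cfg$outlier_sigma_um) else 0
      peak_ok <- !is_outlier
      obs[[ri]]$theta <- c(obs[[ri]]$theta, th)
      obs[[ri]]$y <- c(obs[[ri]]$y, y_obs)
      obs[[ri]]$ok <- c(obs[[ri]]$ok, peak_ok)
      if (cfg$correction) {
        good <- obs[[ri]]$ok
        if (sum(good) >= cfg$bootstrap_points &&
            length(unique(obs[[ri]]$theta[good])) >= 2) {
          fit <- fit_eucentric(list(theta = obs[[ri]]$theta[good],
                                    y = obs[[ri]]$y[good]),
                               drop_outliers = cfg$drop_outliers)
          models[ri, ] <- c(fit$y0, fit$z0)
          fitted[ri] <- TRUE
        }
      }
      log_rows[[(ti - 1) * n_roi + ri]] <- data.frame(
        tilt_index = ti, theta = th, roi = rois$id[ri],
        bis_x_um = rois$x_um[ri], bis_y_um = pred$y,
        err_x_um = err_x, err_y_um = err_y, defocus_err_um = defocus_err,
        y_obs_um = y_obs, peak_ok = peak_ok,
        tracking_iterations = tr$iterations, converged = tr$converged,
        track_residual_nm = sqrt(sum(resid_um^2)) * 1000,
        model = used_model,
        stringsAsFactors = FALSE)
    }
  }
  log <- do.call(rbind, log_rows)
  attr(log, "tracking") <- do.call(rbind, track_rows)
  attr(log, "config") <- cfg
  attr(log, "scheme") <- scheme
  attr(log, "seed") <- seed
  class(log) <- c("acquisition_log", class(log))
  log
}

#' Summarize an acquisition log
#'
#' Per-tilt and overall medians and inter-quartile ranges of the absolute
#' targeting error components and of the defocus error (both raw and as the
#' drift relative to each ROI's first image, the convention used when
#' reporting defocus stability over a series).
#'
#' @param log an [run_bisect_session()] log.
#' @return list with `per_tilt` and `overall` data frames.
#' @export
summarize_session <- function(log) {
  if (nrow(log) == 0) stop_bisectr("empty acquisition log")
  df <- as.data.frame(log)
  first <- df[df$tilt_index == 1, c("roi", "defocus_err_um")]
  names(first)[2] <- "defocus_err_first"
  df <- merge(df, first, by = "roi", sort = FALSE)
  df$defocus_drift_um <- df$defocus_err_um - df$defocus_err_first
  iqr <- function(x) unname(diff(quantile(x, c(0.25, 0.75))))
  stat <- function(d) data.frame(
    n = nrow(d),
    median_err_x_um = median(abs(d$err_x_um)), iqr_err_x_um = iqr(abs(d$err_x_um)),
    median_err_y_um = median(abs(d$err_y_um)), iqr_err_y_um = iqr(abs(d$err_y_um)),
    median_defocus_err_um = median(abs(d$defocus_err_um)),
    iqr_defocus_err_um = iqr(abs(d$defocus_err_um)),
    median_defocus_drift_um = median(abs(d$defocus_drift_um)),
    iqr_defocus_drift_um = iqr(abs(d$defocus_drift_um)))
  per_tilt <- do.call(rbind, lapply(split(df, df$tilt_index), stat))
  per_tilt <- cbind(tilt_index = as.integer(rownames(per_tilt)),
                    theta = df$theta[match(as.integer(rownames(per_tilt)),
                                           df$tilt_index)],
                    per_tilt)
  rownames(per_tilt) <- NULL
  list(per_tilt = per_tilt[order(per_tilt$tilt_index), ], overall = stat(df))
}
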