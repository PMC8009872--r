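#' Rotate a point about the tilt axis
#'
#' Applies the in-plane/height rotation used throughout targeting: a point at
#' perpendicular offset `y` (micrometres, in the untilted plane) and height
#' `z` (micrometres above the plane of rotation) moves, at stage tilt
#' `theta`, to
#' \deqn{y' = y\cos\theta + z\sin\theta, \qquad z' = -y\sin\theta + z\cos\theta.}
#' `y'` is the apparent in-plane position (what image shift must target) and
#' `z'` the height along the beam (what the focus setting must compensate).
#' The along-axis coordinate `x` is invariant under tilting and is not an
#' argument.
#'
#' @param y,z coordinates in micrometres. Vectorized.
#' @param theta tilt angle in degrees; `abs(theta) <= 90`.
#' @return A list with components `y` and `z` (micrometres).
#' @examples
#' rotate_point_about_tilt_axis(2, 0.1, 30)
#' @export
rotate_point_about_tilt_axis <- function(y, z, theta) {
  check_finite(y); check_finite(z); check_finite(theta)
  if (any(abs(theta) > 90)) {
    stop_bisectr("tilt angle must satisfy |theta| <= 90, got %g", max(abs(theta)))
  }
  t <- deg2rad(theta)
  list(y = y * cos(t) + z * sin(t),
       z = -y * sin(t) + z * cos(t))
}

#' Fit the eucentric offset of a target from its tracked positions
#'
#' Given observed apparent in-plane positions \eqn{y_{obs}(\theta)} of one
#' region of interest over several tilt angles, recovers the generating
#' offset \eqn{(y_0, z_0)} by ordinary linear least squares on
#' \eqn{y_{obs} = y_0\cos\theta + z_0\sin\theta}. The fit is closed form:
#' the design matrix has columns \eqn{(\cos\theta, \sin\theta)}.
#'
#' Optionally (`drop_outliers = TRUE`) a second pass removes points whose
#' residual exceeds `outlier_k` times the first-pass RMS residual; large
#' apparent movements at high tilt are typically cross-correlation failures
#' rather than true motion.
#'
#' @param observations data frame (or list) with components `theta`
#'   (degrees) and `y` (micrometres): at least 2 points at 2 distinct angles.
#' @param drop_outliers logical; refit without gross outliers (default off).
#' @param outlier_k residual threshold in units of RMS residual.
#' @return An object of class `eucentric_fit` with fields `y0`, `z0`
#'   (micrometres), `rms_residual`, `n_points`, `n_dropped`.
#' @export
fit_eucentric <- function(observations, drop_outliers = FALSE, outlier_k = 3) {
  theta <- observations$theta
  y <- observations$y
  check_finite(theta, "theta"); check_finite(y, "y")
  if (length(theta) != length(y)) stop_bisectr("theta and y lengths differ")
  if (length(theta) < 2) stop_bisectr("need at least 2 observations")
  if (length(unique(theta)) < 2) {
    stop_bisectr("under-determined eucentric fit: all %d observations at theta = %g",
                 length(theta), theta[1])
  }
  solve_fit <- function(th, yy) {
    A <- cbind(cos(deg2rad(th)), sin(deg2rad(th)))
    sol <- solve(crossprod(A), crossprod(A, yy))
    res <- yy - A %*% sol
    list(y0 = sol[1], z0 = sol[2], rms = sqrt(mean(res^2)), res = res)
  }
  f <- solve_fit(theta, y)
  dropped <- 0L
  if (drop_outliers && f$rms > 0) {
    keep <- abs(f$res) <= outlier_k * f$rms
    if (any(!keep) && sum(keep) >= 2 && length(unique(theta[keep])) >= 2) {
      dropped <- sum(!keep)
      f <- solve_fit(theta[keep], y[keep])
    }
  }
  structure(list(y0 = unname(f$y0), z0 = unname(f$z0),
                 rms_residual = f$rms, n_points = length(theta) - dropped,
                 n_dropped = dropped),
            class = "eucentric_fit")
}

#' @export
print.eucentric_fit <- function(x, ...) {
  cat(sprintf("eucentric fit: y0 = %.4f um, z0 = %.4f um (rms %.4g um, n = %d)\n",
              x$y0, x$z0, x$rms_residual, x$n_points))
  invisible(x)
}

#' Predict the image-shift target and defocus correction for a fitted ROI
#'
#' Evaluates the fitted \eqn{(y_0, z_0)} at tilt `theta`: the first component
#' is the apparent in-plane position that beam-image shift must target, the
#' second the height along the beam that the focus setting must absorb.
#'
#' @param fit an [fit_eucentric()] result (or any list with `y0`, `z0`).
#' @param theta tilt angle in degrees.
#' @return list with `y_target` and `defocus_correction`, micrometres.
#' @export
predict_roi_correction <- function(fit, theta) {
  if (is.null(fit$y0) || is.null(fit$z0)) {
    stop_bisectr("'fit' must carry y0 and z0 components")
  }
  check_finite(fit$y0, "y0"); check_finite(fit$z0, "z0")
  p <- rotate_point_about_tilt_axis(fit$y0, fit$z0, theta)
  list(y_target = p$y, defocus_correction = p$z)
}

#' Construct a beam-image-shift target
#'
#' A region of interest addressed by beam-image shift from a tracking
#' position: `x` along the tilt axis, `y` perpendicular to it (both at zero
#' tilt), `z` the height offset from the tracking area's plane of rotation,
#' and `bis_offset` the image-shift vector from the tracking area.
#'
#' @param id label.
#' @param x,y,z position in micrometres.
#' @param bis_offset length-2 image-shift vector (micrometres); defaults to
#'   `c(x, y)`.
#' @param max_bis_radius_um largest permitted image-shift radius. The
#'   practical electron-optical limit is about 8 micrometres.
#' @export
roi_target <- function(id, x, y, z = 0, bis_offset = c(x, y),
                       max_bis_radius_um = 8) {
  check_finite(x); check_finite(y); check_finite(z)
  if (length(bis_offset) != 2) stop_bisectr("bis_offset must be length 2")
  if (sqrt(sum(bis_offset^2)) > max_bis_radius_um) {
    stop_bisectr("ROI '%s': |bis_offset| = %.2f um exceeds the %g um image-shift radius",
                 as.character(id), sqrt(sum(bis_offset^2)), max_bis_radius_um)
  }
  structure(list(id = id, x = x, y = y, z = z, bis_offset = bis_offset),
            class = "roi_target")
}
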