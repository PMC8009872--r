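# Iterative two-level tracking against a fixed first-image reference.

#' Tracking state for one magnification level
#'
#' Holds the fixed reference image (the first, zero-tilt image of the series
#' at this magnification; it is never replaced by later tilts), the pixel
#' size and the convergence threshold. Thresholds are expressed in nm so
#' that they scale naturally with the field of view when the magnification
#' changes.
#'
#' @param reference numeric matrix, the zero-tilt image at this level.
#' @param level `"low_mag"` or `"high_mag"`.
#' @param pixel_size Angstrom per pixel at this level.
#' @param threshold_nm convergence threshold on the measured residual, nm.
#' @param max_iterations iteration cap for the acquire/measure loop.
#' @export
tracking_state <- function(reference, level = c("low_mag", "high_mag"),
                           pixel_size, threshold_nm, max_iterations = 5) {
  level <- match.arg(level)
  check_finite(pixel_size); check_finite(threshold_nm)
  if (threshold_nm <= 0) stop_bisectr("threshold must be > 0")
  if (!is.matrix(reference)) stop_bisectr("reference must be a matrix")
  structure(list(reference = reference, level = level,
                 pixel_size = pixel_size, threshold_nm = threshold_nm,
                 max_iterations = max_iterations,
                 accumulated_shift_nm = c(0, 0)),
            class = "tracking_state")
}

#' Iteratively track one tilt against the series reference
#'
#' Acquire/measure/correct loop for a single tilt: a new image is acquired,
#' cosine-stretched to the reference (zero-tilt) geometry, and the residual
#' displacement with respect to the fixed first image is measured by
#' filtered cross-correlation. If the residual exceeds the level threshold,
#' the negated shift is handed back to the acquisition callback as an
#' image-shift correction and the cycle repeats, so that the verification
#' image always confirms the applied correction. Non-convergence within
#' `max_iterations` is reported, not raised.
#'
#' @param acquire callback `function(delta_nm)` applying an incremental
#'   image-plane shift correction (`c(x, y)`, nm; specimen scale) and
#'   returning the new image. First call receives `c(0, 0)`.
#' @param state a [tracking_state()].
#' @param theta current tilt angle, degrees.
#' @param axis_angle tilt-axis orientation in the image, degrees.
#' @return list: `total_shift_nm` (accumulated applied correction),
#'   `residual_nm` (last measured residual), `iterations`, `converged`,
#'   `peak_height`.
#' @export
iterative_track <- function(acquire, state, theta, axis_angle = 0) {
  stopifnot(inherits(state, "tracking_state"))
  total <- c(0, 0)
  delta <- c(0, 0)
  resid <- Inf; peak <- NA_real_; converged <- FALSE
  iter <- 0L
  while (iter < state$max_iterations) {
    iter <- iter + 1L
    img <- acquire(delta)
    stretched <- cosine_stretch(img, theta, axis_angle)
    sh <- measure_shift(state$reference, stretched)
    # map the shift measured in stretched geometry back to image geometry:
    # the component perpendicular to the axis is compressed by cos(theta)
    a <- deg2rad(axis_angle); ct <- cos(deg2rad(theta))
    along <- sh$dx * cos(a) + sh$dy * sin(a)
    perp <- (-sh$dx * sin(a) + sh$dy * cos(a)) * ct
    d_img <- c(along * cos(a) - perp * sin(a),
               along * sin(a) + perp * cos(a))
    shift_nm <- d_img * state$pixel_size / 10
    resid <- sqrt(sum(shift_nm^2))
    peak <- sh$peak_height
    if (resid <= state$threshold_nm) { converged <- TRUE; break }
    delta <- -shift_nm
    total <- total + delta
  }
  list(total_shift_nm = total, residual_nm = resid, iterations = iter,
       converged = converged, peak_height = peak)
}
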