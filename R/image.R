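# In-memory image operations used by tracking: cosine stretching and
# filtered cross-correlation shift measurement.

#' Cosine-stretch a tilted image back to zero-tilt geometry
#'
#' A specimen plane tilted by `theta` appears foreshortened by
#' `cos(theta)` along the in-plane direction perpendicular to the tilt axis.
#' This resamples the image by `1/cos(theta)` along that direction
#' (bilinear interpolation, output dimensions unchanged, out-of-field
#' samples filled with the image mean) so that it can be correlated against
#' an untilted reference.
#'
#' @param image numeric matrix.
#' @param theta tilt angle, degrees; `abs(theta) < 90`.
#' @param axis_angle orientation of the tilt axis in the image, degrees
#'   counter-clockwise from the column (x) direction.
#' @param fill value for samples falling outside the input; default mean.
#' @return Matrix of the same dimensions.
#' @export
cosine_stretch <- function(image, theta, axis_angle = 0, fill = NULL) {
  check_finite(theta); check_finite(axis_angle)
  if (abs(theta) >= 90) stop_bisectr("cannot stretch at |theta| >= 90 (infinite factor)")
  if (theta == 0 && axis_angle == 0) return(image)
  fill <- fill %||% mean(image)
  nr <- nrow(image); nc <- ncol(image)
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  u <- rep(seq_len(nc) - cc, each = nr)   # column offsets (x)
  v <- rep(seq_len(nr) - rc, times = nc)  # row offsets (y)
  a <- deg2rad(axis_angle)
  ct <- cos(deg2rad(theta))
  # rotate into axis frame, compress the perpendicular coordinate, rotate back
  along <- u * cos(a) + v * sin(a)
  perp <- (-u * sin(a) + v * cos(a)) * ct
  us <- along * cos(a) - perp * sin(a)
  vs <- along * sin(a) + perp * cos(a)
  out <- bilinear_interp(image, vs + rc, us + cc, fill = fill)
  matrix(out, nr, nc)
}

#' Measure the translation between two images by cross-correlation
#'
#' Computes the shift `(dx, dy)` (columns, rows; pixels) that maximizes the
#' circular cross-correlation between `image` and `reference`, i.e.
#' `image ~ reference` translated by `(dx, dy)`. Both images are
#' mean-subtracted, Hann-apodized and band-pass filtered before
#' correlation (low-dose robustness); the peak is localized to sub-pixel
#' precision by separable parabolic interpolation. Ties between equal peaks
#' are broken toward the smallest-magnitude shift.
#'
#' @param reference,image numeric matrices of equal dimensions, non-constant.
#' @param lowpass,highpass Gaussian band edges in cycles/pixel.
#' @param window apply a Hann window before correlation.
#' @return list with `dx`, `dy` (pixels) and `peak_height` (normalized
#'   correlation at the peak, in `[-1, 1]` up to interpolation).
#' @export
measure_shift <- function(reference, image, lowpass = 0.35, highpass = 0.02,
                          window = TRUE) {
  if (!all(dim(reference) == dim(image))) stop_bisectr("image dimensions differ")
  if (sd(reference) == 0 || sd(image) == 0) {
    stop_bisectr("cannot correlate a flat (zero-variance) image")
  }
  nr <- nrow(reference); nc <- ncol(reference)
  w <- if (window) hann2(nr, nc) else 1
  h <- bandpass_transfer(nr, nc, lo = highpass, hi = lowpass)
  fr <- fft((reference - mean(reference)) * w) * h
  fi <- fft((image - mean(image)) * w) * h
  cc <- Re(fft(fi * Conj(fr), inverse = TRUE)) / length(fr)
  norm <- sqrt(sum(Mod(fr)^2) * sum(Mod(fi)^2)) / length(fr)
  peak <- max(cc)
  cand <- which(cc >= peak - 1e-12 * abs(peak))
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  ri <- (cand - 1) %% nr + 1
  ci <- (cand - 1) %/% nr + 1
  dyc <- wrap(ri, nr); dxc <- wrap(ci, nc)
  pick <- which.min(dxc^2 + dyc^2)
  ri <- ri[pick]; ci <- ci[pick]
  # parabolic sub-pixel refinement with circular neighbours
  nb <- function(i, n, d) (i - 1 + d) %% n + 1
  py <- c(cc[nb(ri, nr, -1), ci], cc[ri, ci], cc[nb(ri, nr, 1), ci])
  px <- c(cc[ri, nb(ci, nc, -1)], cc[ri, ci], cc[ri, nb(ci, nc, 1)])
  sub <- function(p) {
    den <- p[1] - 2 * p[2] + p[3]
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (p[1] - p[3]) / den))
  }
  list(dx = wrap(ci, nc) + sub(px),
       dy = wrap(ri, nr) + sub(py),
       peak_height = peak / norm)
}
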