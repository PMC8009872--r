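# Rotation matrices, centred FFT helpers and central-slice access used by
# simulation, scoring and reconstruction.

rot_x <- function(a) { a <- deg2rad(a); matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3) }
rot_y <- function(a) { a <- deg2rad(a); matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3) }
rot_z <- function(a) { a <- deg2rad(a); matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) }

#' Rotation matrices for tilting and particle orientation
#'
#' `tilt_rotation()` maps specimen coordinates to camera coordinates at a
#' given stage tilt: with the axis along image x, a point at (y, z) appears
#' at `y' = y cos(theta) + z sin(theta)` with height
#' `z' = -y sin(theta) + z cos(theta)` (positive tilt moves +y toward +z).
#' `euler_zyz()` is the intrinsic ZYZ particle orientation. The combined
#' projection orientation of a particle is
#' `tilt_rotation(...) %*% euler_zyz(...)` (tilt composes on the left).
#'
#' @param theta tilt angle, degrees. @param axis_angle in-plane tilt-axis
#'   orientation, degrees from image x.
#' @return 3x3 rotation matrix.
#' @export
tilt_rotation <- function(theta, axis_angle = 0) {
  rot_z(axis_angle) %*% rot_x(-theta) %*% rot_z(-axis_angle)
}

#' @rdname tilt_rotation
#' @param e1,e2,e3 ZYZ Euler angles, degrees.
#' @export
euler_zyz <- function(e1, e2, e3) {
  rot_z(e1) %*% rot_y(e2) %*% rot_z(e3)
}

# Centred FFTs: both the real-space origin and DC sit at floor(n/2)+1.
fftc <- function(x) fftshift(fft(ifftshift(x)))
ifftc <- function(x) fftshift(fft(ifftshift(x), inverse = TRUE)) / length(x)

# Centred integer frequency offsets of an n-point axis.
kgrid <- function(n) seq_len(n) - 1 - floor(n / 2)

# Oversampled reference transform: the volume is zero-padded in real space
# by `pad` before the centred FFT, so central slices are interpolated on a
# grid `pad` times finer -- the standard trick to keep trilinear gridding
# error small.
ref_transform <- function(vol, pad = 2) {
  n <- dim(vol)[1]
  np <- n * pad
  big <- array(0, c(np, np, np))
  off <- floor((np - n) / 2)
  big[off + seq_len(n), off + seq_len(n), off + seq_len(n)] <- vol
  structure(list(vhat = fftc(big), box = n, pad = pad), class = "ref_transform")
}

# Extract the central slice of a reference transform (or a plain centred 3D
# FT, pad = 1) at orientation R: samples at t(R) %*% (kx, ky, 0). Returns a
# centred complex box x box matrix.
extract_slice <- function(ref, R, n = NULL) {
  if (inherits(ref, "ref_transform")) {
    vhat <- ref$vhat; pad <- ref$pad; n <- n %||% ref$box
  } else {
    vhat <- ref; pad <- 1; n <- n %||% dim(ref)[1]
  }
  k <- kgrid(n)
  kx <- rep(k, times = n)   # column-major: x fastest
  ky <- rep(k, each = n)
  q <- t(R) %*% rbind(kx, ky, 0) * pad
  ctr <- floor(dim(vhat)[1] / 2) + 1
  matrix(trilinear_interp(vhat, q[1, ] + ctr, q[2, ] + ctr, q[3, ] + ctr), n, n)
}

# Phase ramp that translates an image by (dx, dy) pixels when multiplied
# onto its centred FT. Reconstruction-side images are stored [x, y] (first
# index x), so the ramp is outer(ramp_x, ramp_y).
phase_ramp <- function(n, dx, dy) {
  k <- kgrid(n) / n
  outer(exp(-2i * pi * k * dx), exp(-2i * pi * k * dy))
}

# Real projection image ([x, y] layout) from a centred complex slice.
slice_to_image <- function(slice) Re(ifftc(slice))

# Centred FT of a real [x, y] image.
image_to_slice <- function(img) fftc(img)
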