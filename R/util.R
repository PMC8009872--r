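# Internal numerical helpers: angles, FFT index bookkeeping, interpolation.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bisectr <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_finite <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_bisectr("'%s' must be finite numeric, got: %s", name,
                 paste(utils::head(x, 3), collapse = ", "))
  }
  invisible(x)
}

# Circular roll of indices: element i of the result takes input index i - k.
roll_index <- function(n, k) ((seq_len(n) - 1 - k) %% n) + 1

#' Centre or de-centre the zero-frequency sample of an FFT array
#'
#' `fftshift()` moves the DC sample of an unshifted discrete Fourier
#' transform to the centre (`floor(n/2) + 1` along each dimension);
#' `ifftshift()` is its exact inverse for odd and even sizes alike.
#' Works on vectors, matrices and 3D arrays.
#'
#' @param x numeric or complex vector, matrix or 3D array.
#' @return Array of the same shape.
#' @export
fftshift <- function(x) shift_nd(x, floor)

#' @rdname fftshift
#' @export
ifftshift <- function(x) shift_nd(x, ceiling)

shift_nd <- function(x, half) {
  if (is.null(dim(x))) {
    return(x[roll_index(length(x), half(length(x) / 2))])
  }
  d <- dim(x)
  idx <- lapply(d, function(n) roll_index(n, half(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Centred frequency coordinate in cycles/pixel: position floor(n/2)+1 is DC.
freq_centered <- function(n, d = 1) (seq_len(n) - 1 - floor(n / 2)) / (n * d)

# Unshifted FFT frequency coordinate (DC first), cycles/pixel.
freq_fft <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1))
  k / (n * d)
}

# Bilinear interpolation on a matrix at fractional (row, col) positions.
# Out-of-range samples return `fill`. Supports complex matrices.
bilinear_interp <- function(m, ri, ci, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  r <- pmin(pmax(ri, 1), nr)
  c <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(r), nr - 1)
  c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0
  fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- m[i00]       * (1 - fr) * (1 - fc) +
       m[i00 + 1]   * fr       * (1 - fc) +
       m[i00 + nr]  * (1 - fr) * fc +
       m[i00 + nr + 1] * fr    * fc
  v[!ok] <- fill
  v
}

# Trilinear interpolation in a 3D (possibly complex) array at fractional
# (i, j, k) positions; out-of-range -> 0.
trilinear_interp <- function(a, xi, yi, zi) {
  d <- dim(a)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  x <- pmin(pmax(xi, 1), d[1]); y <- pmin(pmax(yi, 1), d[2])
  z <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n1 <- d[1]; n12 <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * n1 + (z0 - 1) * n12
  v <-
    a[i000]            * (1 - fx) * (1 - fy) * (1 - fz) +
    a[i000 + 1]        * fx       * (1 - fy) * (1 - fz) +
    a[i000 + n1]       * (1 - fx) * fy       * (1 - fz) +
    a[i000 + n1 + 1]   * fx       * fy       * (1 - fz) +
    a[i000 + n12]      * (1 - fx) * (1 - fy) * fz +
    a[i000 + n12 + 1]  * fx       * (1 - fy) * fz +
    a[i000 + n12 + n1] * (1 - fx) * fy       * fz +
    a[i000 + n12 + n1 + 1] * fx   * fy       * fz
  v[!ok] <- 0
  v
}

# 2D Hann window, separable.
hann2 <- function(nr, nc = nr) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wr, wc)
}

# Gaussian-edged band-pass transfer function on the unshifted FFT grid,
# cutoffs in cycles/pixel.
bandpass_transfer <- function(nr, nc, lo = 0.02, hi = 0.35) {
  fr <- freq_fft(nr)
  fc <- freq_fft(nc)
  f2 <- outer(fr^2, fc^2, `+`)
  h <- exp(-f2 / (2 * hi^2))
  if (lo > 0) h <- h * (1 - exp(-f2 / (2 * lo^2)))
  h
}

# Relativistic electron wavelength in Angstrom for voltage in kV.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

# Radial shell index (1-based) for every element of a centred n x n (x n)
# frequency grid; shell width is one Fourier pixel.
shell_index <- function(dims) {
  ax <- lapply(dims, function(n) freq_centered(n) * n)  # centred int offsets
  if (length(dims) == 2) {
    r <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  } else {
    r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  }
  round(r) + 1L
}

# Per-shell mean of `values`; returns a length-`nshell` vector (NA for
# shells with no samples). Shells beyond `nshell` are dropped.
shell_mean <- function(values, shells, nshell = max(shells)) {
  keep <- shells <= nshell
  s <- shells[keep]
  sums <- rowsum(as.numeric(values[keep]), s, reorder = TRUE)
  cnt <- tabulate(s, nbins = nshell)
  out <- rep(NA_real_, nshell)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out / ifelse(cnt > 0, cnt, NA)
}

# Per-shell sum, length-`nshell` (0 for empty shells).
shell_sum <- function(values, shells, nshell = max(shells)) {
  keep <- shells <= nshell
  s <- shells[keep]
  sums <- rowsum(as.numeric(values[keep]), s, reorder = TRUE)
  out <- rep(0, nshell)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

# Derive a child seed (< 2^31) from a base seed and a stream label.
# Arithmetic in doubles (exact below 2^53) so chained derivations of
# already-large seeds cannot overflow 32-bit integers.
derive_seed <- function(seed, stream) {
  s <- as.numeric(seed) %% 2147483562
  as.integer((s * 48271 + as.numeric(stream) * 104729) %% 2147483562) + 1L
}
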