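# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# A short dose-symmetric scheme for fast closed-loop session tests.
short_scheme <- function(n_pairs = 3, dose = 5) {
  generate_grouped_dose_symmetric(n_pairs * 3, 3, 1, dose_per_tilt = dose)
}

# Independent brute-force sub-pixel shift oracle: cross-correlation on a
# k-times upsampled grid via zero-padded FFTs (no parabolic interpolation).
oracle_shift <- function(reference, image, k = 8) {
  n <- nrow(reference)
  w <- hann2_test(n)
  fr <- stats::fft((reference - mean(reference)) * w)
  fi <- stats::fft((image - mean(image)) * w)
  cc <- fi * Conj(fr)
  big <- matrix(0+0i, n * k, n * k)
  h <- n / 2
  idx <- c(1:h, (n * k - h + 1):(n * k))
  big[idx, idx] <- cc[c(1:h, (h + 1):n), c(1:h, (h + 1):n)]
  r <- Re(stats::fft(big, inverse = TRUE))
  p <- unname(which(r == max(r), arr.ind = TRUE)[1, ])
  wrap <- function(i, nn) ifelse(i - 1 > nn / 2, i - 1 - nn, i - 1)
  c(dx = wrap(p[2], n * k) / k, dy = wrap(p[1], n * k) / k)
}

hann2_test <- function(n) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  outer(w, w)
}

# Band-limited (low-passed) correlation of two equal-size arrays.
bandlimited_cor <- function(a, b, fmax_px) {
  lp <- function(v) {
    vh <- stats::fft(v)
    d <- dim(v)
    ax <- lapply(d, function(n) {
      k <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1)) / n
      k
    })
    if (length(d) == 2) {
      fr <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
    } else {
      fr <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
    }
    vh[fr > fmax_px] <- 0
    Re(stats::fft(vh, inverse = TRUE)) / length(v)
  }
  x <- lp(a); y <- lp(b)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# Soft spherical support mask over the centred box, radius in voxels.
soft_sphere <- function(box, radius, edge = 1.5) {
  k <- seq_len(box) - 1 - floor(box / 2)
  r <- sqrt(outer(outer(k^2, k^2, `+`), k^2, `+`))
  1 / (1 + exp((r - radius) / edge))
}

# Small noiseless-ish particle dataset reused by recon/refine tests.
tiny_particle_sim <- function(n_particles = 4, noise_sd = 1e-4, seed = 4,
                              dose_b_slope = 0, image_n = 256, ...) {
  simulate_particle_dataset(
    n_particles = n_particles, scheme = scheme_fixture("pm36"),
    n_series = 1, box = 32, pixel_size = 3, image_n = image_n,
    dose_b_slope = dose_b_slope, noise_sd = noise_sd, seed = seed, ...)
}
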