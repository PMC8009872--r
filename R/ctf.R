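# Astigmatic CTF model, synthetic tilted micrographs, tilt-corrected power
# spectra and per-tilt defocus fitting.

#' Microscope and defocus parameters of an astigmatic CTF
#'
#' Defocus is in Angstrom with underfocus positive; `defocus1 >= defocus2`
#' and `astig_angle` (azimuth of `defocus1`) is normalized to `[-90, 90)`.
#' Values violating the ordering are canonicalized by swapping the pair and
#' rotating the angle by 90 degrees, which leaves the model invariant.
#'
#' @param defocus1,defocus2 max/min defocus, Angstrom (underfocus positive).
#' @param astig_angle azimuth of `defocus1`, degrees.
#' @param voltage kV. @param cs spherical aberration, mm.
#' @param amplitude_contrast fraction in `[0, 1)`.
#' @param phase_shift additional phase, radians.
#' @param pixel_size Angstrom/pixel of the images this CTF refers to.
#' @export
ctf_params <- function(defocus1, defocus2 = defocus1, astig_angle = 0,
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                       phase_shift = 0, pixel_size = 1) {
  check_finite(defocus1); check_finite(defocus2); check_finite(astig_angle)
  if (defocus1 < defocus2) {
    tmp <- defocus1; defocus1 <- defocus2; defocus2 <- tmp
    astig_angle <- astig_angle + 90
  }
  astig_angle <- ((astig_angle + 90) %% 180) - 90
  structure(list(defocus1 = defocus1, defocus2 = defocus2,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift, pixel_size = pixel_size),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf("CTF: dz = %.0f/%.0f A at %.1f deg, %g kV, Cs %g mm, w %g, %g A/px\n",
              x$defocus1, x$defocus2, x$astig_angle, x$voltage, x$cs,
              x$amplitude_contrast, x$pixel_size))
  invisible(x)
}

#' Evaluate the astigmatic contrast transfer function
#'
#' \deqn{CTF(f,\phi) = -\sin(\chi + \phi_a)} with
#' \eqn{\chi = \pi\lambda\Delta z(\phi) f^2 - \frac{\pi}{2} C_s \lambda^3 f^4
#' + \Delta\phi}, local defocus
#' \eqn{\Delta z(\phi) = \frac12[(z_1+z_2) + (z_1-z_2)\cos 2(\phi-\phi_a)]}
#' and \eqn{\phi_a = \arcsin(w)} the amplitude-contrast phase.
#'
#' @param fx,fy spatial frequency components, 1/Angstrom (vectorized).
#' @param params a [ctf_params()].
#' @param defocus_offset additive defocus offset in Angstrom applied to both
#'   components (used for per-particle height corrections).
#' @return CTF values in `[-1, 1]`.
#' @export
ctf_2d <- function(fx, fy, params, defocus_offset = 0) {
  lambda <- electron_wavelength(params$voltage)
  cs_A <- params$cs * 1e7
  f2 <- fx^2 + fy^2
  phi <- atan2(fy, fx)
  z_mean <- 0.5 * (params$defocus1 + params$defocus2) + defocus_offset
  z_diff <- 0.5 * (params$defocus1 - params$defocus2)
  dz <- z_mean + z_diff * cos(2 * (phi - deg2rad(params$astig_angle)))
  chi <- pi * lambda * dz * f2 - 0.5 * pi * cs_A * lambda^3 * f2^2 +
    params$phase_shift
  -sin(chi + asin(params$amplitude_contrast))
}

# Centred n x n CTF image on the frequency grid of pixel_size.
ctf_image <- function(n, params, defocus_offset = 0) {
  f <- freq_centered(n, params$pixel_size)
  fx <- matrix(f, n, n, byrow = TRUE)   # columns = x
  fy <- matrix(f, n, n)
  matrix(ctf_2d(fx, fy, params, defocus_offset), n, n)
}

#' Per-tilt imaging geometry
#'
#' The orientation of the tilt axis in the image plane (degrees,
#' counter-clockwise from the image x axis), the tilt angle, and an optional
#' in-plane alignment transform (2x2 matrix + shift as in `.xf` files).
#'
#' @param tilt_axis_angle,tilt_angle degrees; `abs(tilt_angle) < 90`.
#' @param xf length-6 numeric `(a11 a12 a21 a22 dx dy)` or NULL (identity).
#' @export
tilt_geometry <- function(tilt_axis_angle = 0, tilt_angle = 0, xf = NULL) {
  check_finite(tilt_axis_angle); check_finite(tilt_angle)
  if (abs(tilt_angle) >= 90) stop_bisectr("|tilt_angle| must be < 90")
  if (is.null(xf)) xf <- c(1, 0, 0, 1, 0, 0)
  if (length(xf) != 6) stop_bisectr("xf must have 6 elements")
  structure(list(tilt_axis_angle = tilt_axis_angle, tilt_angle = tilt_angle,
                 xf = xf), class = "tilt_geometry")
}

# Height (Angstrom, along the beam) of image position (dx, dy) px from the
# field centre, for the plane through the centre containing the tilt axis.
tilt_height_A <- function(dx_px, dy_px, geom, pixel_size) {
  a <- deg2rad(geom$tilt_axis_angle)
  perp <- (-dx_px * sin(a) + dy_px * cos(a)) * pixel_size
  perp * tan(deg2rad(geom$tilt_angle))
}

#' Simulate a tilted micrograph with a spatially varying CTF
#'
#' A white-noise specimen is modulated by a CTF whose defocus varies across
#' the field according to the tilt plane through the field centre: the local
#' defocus at image position r is the nominal defocus plus
#' `height(r) = d_perp(r) * tan(tilt)`, where `d_perp` is the distance from
#' the tilt axis. The field is synthesized by filtering with a bank of CTFs
#' at stepped defocus planes (step <= `plane_step_A`) and blending linearly
#' between planes, then Poisson counting noise at `dose` is added.
#' Ground-truth parameters are attached as attributes.
#'
#' @param params [ctf_params()] at the field centre (tilt-plane origin).
#' @param geom [tilt_geometry()].
#' @param dose e-/A^2. @param seed integer. @param n image side (>= 256).
#' @param contrast specimen contrast fraction.
#' @param plane_step_A defocus discretization of the gradient.
#' @return `n x n` matrix with attributes `params`, `geom`, `dose`.
#' @export
synth_tilted_micrograph <- function(params, geom, dose = 3, seed = 1,
                                    n = 512, contrast = 0.12,
                                    plane_step_A = 100) {
  if (n < 256) stop_bisectr("image size must be >= 256 px")
  set.seed(as.integer(seed))
  px <- params$pixel_size
  u <- matrix(rnorm(n * n), n)
  uh <- fft(u)
  # local defocus offsets across the field
  idx <- seq_len(n) - (n + 1) / 2
  dxm <- matrix(idx, n, n, byrow = TRUE)
  dym <- matrix(idx, n, n)
  h <- tilt_height_A(dxm, dym, geom, px)
  rng <- range(h)
  if (diff(rng) < plane_step_A) {
    planes <- mean(rng)
  } else {
    planes <- seq(rng[1], rng[2], length.out = ceiling(diff(rng) / plane_step_A) + 1)
  }
  f <- freq_fft(n, px)
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  imgs <- lapply(planes, function(dz) {
    Re(fft(uh * ctf_2d(fx, fy, params, defocus_offset = dz),
           inverse = TRUE)) / (n * n)
  })
  if (length(planes) == 1) {
    s <- imgs[[1]]
  } else {
    step <- planes[2] - planes[1]
    pos <- (h - planes[1]) / step
    i0 <- pmin(pmax(floor(pos), 0), length(planes) - 2)
    fr <- pos - i0
    s <- matrix(0, n, n)
    for (k in seq_len(length(planes) - 1)) {
      sel <- i0 == (k - 1)
      if (!any(sel)) next
      s[sel] <- imgs[[k]][sel] * (1 - fr[sel]) + imgs[[k + 1]][sel] * fr[sel]
    }
  }
  s <- s / sd(s)
  dose_px <- dose * px^2
  img <- matrix(rpois(n * n, dose_px * pmax(0.02, 1 + contrast * pmin(pmax(s, -3), 3))),
                n, n) / dose_px - 1
  attr(img, "params") <- params
  attr(img, "geom") <- geom
  attr(img, "dose") <- dose
  img
}

#' Tilt-corrected tiled power spectrum
#'
#' Averages the power spectra of overlapping tiles after rescaling each
#' tile's frequency axis from its local defocus (predicted from the known
#' tilt geometry at the tile centre) to the field-centre defocus: Thon ring
#' radii scale as \eqn{1/\sqrt{\Delta z}}, so resampling each tile spectrum
#' radially by \eqn{\sqrt{\Delta z_c/\Delta z_{local}}} aligns the rings
#' before averaging, keeping them sharp despite the defocus gradient.
#' With `correct = FALSE` (or zero tilt) this reduces to plain tiled
#' averaging.
#'
#' @param image micrograph matrix.
#' @param geom [tilt_geometry()]; `abs(tilt) < 90`.
#' @param tile_size tile side, px (<= image size); 50 percent overlap.
#' @param center_defocus_hint approximate mean defocus at the field centre,
#'   Angstrom; needed to convert the height gradient into a frequency
#'   rescaling. See [estimate_center_defocus()].
#' @param pixel_size Angstrom/px.
#' @param correct apply the tilt correction (default TRUE).
#' @return Centred `tile_size x tile_size` average power spectrum with
#'   attribute `pixel_size`.
#' @export
tilted_power_spectrum <- function(image, geom, tile_size = 128,
                                  center_defocus_hint, pixel_size,
                                  correct = TRUE) {
  n <- nrow(image)
  if (tile_size > n) stop_bisectr("tile_size exceeds image size")
  if (abs(geom$tilt_angle) >= 90) stop_bisectr("|tilt| must be < 90")
  starts <- unique(c(seq(1, n - tile_size + 1, by = tile_size %/% 2)))
  acc <- matrix(0, tile_size, tile_size)
  cnt <- 0
  half <- (n + 1) / 2
  for (sy in starts) for (sx in starts) {
    tile <- image[sy:(sy + tile_size - 1), sx:(sx + tile_size - 1)]
    ps <- fftshift(Mod(fft(tile - mean(tile)))^2) / tile_size^2
    if (correct && geom$tilt_angle != 0) {
      cx <- sx + (tile_size - 1) / 2 - half
      cy <- sy + (tile_size - 1) / 2 - half
      z_local <- center_defocus_hint + tilt_height_A(cx, cy, geom, pixel_size)
      if (z_local <= 0) next
      sc <- sqrt(center_defocus_hint / z_local)  # sampling radius factor
      ctr <- floor(tile_size / 2) + 1
      ii <- rep(seq_len(tile_size) - ctr, times = tile_size)
      jj <- rep(seq_len(tile_size) - ctr, each = tile_size)
      ps <- matrix(bilinear_interp(ps, ii * sc + ctr, jj * sc + ctr, fill = 0),
                   tile_size, tile_size)
    }
    acc <- acc + ps
    cnt <- cnt + 1
  }
  out <- acc / cnt
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Radial average of a centred spectrum
#' @param spectrum centred 2D power spectrum.
#' @param pixel_size Angstrom/px.
#' @return list with `freq` (1/Angstrom) and `value` per one-pixel shell.
#' @export
radial_average <- function(spectrum, pixel_size) {
  n <- nrow(spectrum)
  sh <- shell_index(dim(spectrum))
  nsh <- floor(n / 2)
  list(freq = (seq_len(nsh) - 1) / (n * pixel_size),
       value = shell_mean(spectrum, sh, nsh))
}

# Smooth per-shell background: polynomial of given order fitted to the
# radial average over the fit band, evaluated at every pixel's radius.
spectrum_background <- function(spectrum, pixel_size, fmin, fmax, order = 4) {
  ra <- radial_average(spectrum, pixel_size)
  sel <- ra$freq >= fmin & ra$freq <= fmax & !is.na(ra$value)
  fit <- lm(v ~ poly(f, degree = order),
            data = data.frame(f = ra$freq[sel], v = ra$value[sel]))
  n <- nrow(spectrum)
  f1 <- freq_centered(n, pixel_size)
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  bg <- matrix(NA_real_, n, n)
  inside <- fr >= fmin & fr <= fmax
  bg[inside] <- stats::predict(fit, newdata = data.frame(f = fr[inside]))
  bg
}

#' Estimate the field-centre mean defocus from near-axis tiles
#'
#' Coarse, astigmatism-free defocus search used to seed the tilt-corrected
#' power spectrum: only tiles whose centres lie close to the tilt axis
#' (small height, hence small defocus offset) are averaged, and the radial
#' average is correlated against the model `|CTF|` over a defocus grid.
#'
#' @inheritParams tilted_power_spectrum
#' @param search list with `min`, `max`, `step` (Angstrom).
#' @param params0 [ctf_params()] carrying the microscope constants.
#' @param fit_band frequency band `c(fmin, fmax)` in 1/Angstrom.
#' @return Mean defocus estimate, Angstrom.
#' @export
estimate_center_defocus <- function(image, geom, params0, search,
                                    tile_size = 128, pixel_size = 1,
                                    fit_band = c(1 / 30, 1 / 8)) {
  n <- nrow(image)
  starts <- unique(c(seq(1, n - tile_size + 1, by = tile_size %/% 2)))
  half <- (n + 1) / 2
  acc <- matrix(0, tile_size, tile_size); cnt <- 0
  max_h <- 150  # Angstrom: keep the defocus spread of selected tiles small
  for (sy in starts) for (sx in starts) {
    cx <- sx + (tile_size - 1) / 2 - half
    cy <- sy + (tile_size - 1) / 2 - half
    if (abs(tilt_height_A(cx, cy, geom, pixel_size)) > max_h &&
        geom$tilt_angle != 0) next
    tile <- image[sy:(sy + tile_size - 1), sx:(sx + tile_size - 1)]
    acc <- acc + fftshift(Mod(fft(tile - mean(tile)))^2) / tile_size^2
    cnt <- cnt + 1
  }
  if (cnt == 0) stop_bisectr("no tiles near the tilt axis")
  ra <- radial_average(acc / cnt, pixel_size)
  sel <- ra$freq >= fit_band[1] & ra$freq <= fit_band[2] & !is.na(ra$value)
  f <- ra$freq[sel]
  bg <- stats::fitted(lm(v ~ poly(f, 4), data = data.frame(f = f, v = ra$value[sel])))
  obs <- ra$value[sel] - bg
  grid <- seq(search$min, search$max, by = search$step)
  score <- vapply(grid, function(dz) {
    p <- utils::modifyList(params0, list(defocus1 = dz, defocus2 = dz))
    m <- abs(ctf_2d(f, 0, p))
    suppressWarnings(stats::cor(obs, m))
  }, numeric(1))
  grid[which.max(score)]
}

#' Fit an astigmatic CTF to a (tilt-corrected) power spectrum
#'
#' Two-stage fit: a grid search over mean defocus using the
#' background-subtracted radial average, followed by Nelder-Mead refinement
#' of `(defocus1, defocus2, astig_angle)` maximizing the normalized
#' cross-correlation between the model `|CTF|` and the background-subtracted
#' spectrum over the fit annulus. The fit score is that correlation; the fit
#' resolution is the finest shell at which a sliding-window ring correlation
#' between model and spectrum stays above 0.5.
#'
#' @param spectrum centred power spectrum from [tilted_power_spectrum()].
#' @param search list `(min, max, step)` for the mean-defocus grid, Angstrom;
#'   must bracket the truth.
#' @param params0 [ctf_params()] with the microscope constants (defocus
#'   entries ignored).
#' @param fit_band frequency annulus `c(fmin, fmax)`, 1/Angstrom.
#' @param bg_order background polynomial order.
#' @return list: `params` (fitted [ctf_params()]), `fit_score`,
#'   `fit_resolution_A`.
#' @export
fit_astigmatic_ctf <- function(spectrum, search, params0,
                               fit_band = c(1 / 30, 1 / 8), bg_order = 4) {
  if (!is.list(search) || is.null(search$min) || search$max <= search$min) {
    stop_bisectr("degenerate defocus search range")
  }
  px <- attr(spectrum, "pixel_size") %||% params0$pixel_size
  n <- nrow(spectrum)
  bg <- spectrum_background(spectrum, px, fit_band[1], fit_band[2], bg_order)
  f1 <- freq_centered(n, px)
  fxm <- matrix(f1, n, n, byrow = TRUE)
  fym <- matrix(f1, n, n)
  fr <- sqrt(fxm^2 + fym^2)
  ann <- which(fr >= fit_band[1] & fr <= fit_band[2] & !is.na(bg))
  obs <- spectrum[ann] - bg[ann]
  obs <- obs - mean(obs)
  fx <- fxm[ann]; fy <- fym[ann]
  ncc <- function(z1, z2, ang) {
    p <- utils::modifyList(params0,
                           list(defocus1 = z1, defocus2 = z2, astig_angle = ang))
    m <- abs(ctf_2d(fx, fy, p))
    m <- m - mean(m)
    sum(obs * m) / sqrt(sum(obs^2) * sum(m^2))
  }
  grid <- seq(search$min, search$max, by = search$step %||% 250)
  s1 <- vapply(grid, function(dz) ncc(dz, dz, 0), numeric(1))
  z_best <- grid[which.max(s1)]
  # local refinement; astigmatism parameterized as (mean, diff, angle)
  obj <- function(par) -ncc(par[1] + par[2] / 2, par[1] - par[2] / 2, par[3])
  fit <- optim(c(z_best, 200, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  # restart at +/-45 deg to avoid the astigmatism-angle local optimum
  for (a0 in c(-45, 45)) {
    alt <- optim(c(z_best, 200, a0), obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-8))
    if (alt$value < fit$value) fit <- alt
  }
  par <- fit$par
  params <- utils::modifyList(params0,
                              list(defocus1 = par[1] + abs(par[2]) / 2,
                                   defocus2 = par[1] - abs(par[2]) / 2,
                                   astig_angle = if (par[2] >= 0) par[3] else par[3] + 90))
  params <- do.call(ctf_params, params[c("defocus1", "defocus2", "astig_angle",
                                         "voltage", "cs", "amplitude_contrast",
                                         "phase_shift", "pixel_size")])
  score <- -fit$value
  # fit resolution: sliding-window correlation of the 1D radial profiles of
  # the background-subtracted spectrum and the fitted |CTF| model
  model <- abs(ctf_image(n, params))
  sh <- shell_index(dim(spectrum))
  nsh <- floor(n / 2)
  shf <- (seq_len(nsh) - 1) / (n * px)
  spec_c <- spectrum - ifelse(is.na(bg), 0, bg)
  prof_s <- shell_mean(spec_c, sh, nsh)
  prof_m <- shell_mean(model, sh, nsh)
  win <- 4L
  valid <- which(shf >= fit_band[1] & shf <= fit_band[2])
  rc <- vapply(valid, function(s) {
    w <- max(min(valid), s - win):min(max(valid), s + win)
    r <- suppressWarnings(stats::cor(prof_s[w], prof_m[w]))
    if (is.na(r)) 0 else r
  }, numeric(1))
  # shells below the first CTF zero carry no ring information: start at the
  # first shell where the ring correlation locks on, then walk outward
  res_A <- 1 / fit_band[1]
  lock <- which(rc >= 0.5)[1]
  if (!is.na(lock)) {
    run_end <- lock
    while (run_end < length(valid) && rc[run_end + 1] >= 0.5) run_end <- run_end + 1
    res_A <- 1 / shf[valid[run_end]]
  }
  list(params = params, fit_score = score, fit_resolution_A = res_A)
}

#' Mean Thon-ring contrast of a spectrum beyond the first zero
#'
#' Diagnostic used to compare corrected and uncorrected tilted spectra: the
#' standard deviation of the background-subtracted radial oscillation over
#' the fit band, normalized by the local background level.
#'
#' @inheritParams fit_astigmatic_ctf
#' @param pixel_size Angstrom/px.
#' @export
ring_contrast <- function(spectrum, pixel_size, fit_band = c(1 / 20, 1 / 8)) {
  ra <- radial_average(spectrum, pixel_size)
  sel <- ra$freq >= fit_band[1] & ra$freq <= fit_band[2] & !is.na(ra$value)
  f <- ra$freq[sel]; v <- ra$value[sel]
  bg <- stats::fitted(lm(v ~ poly(f, 4)))
  sd(v - bg) / mean(bg)
}

#' Per-tilt astigmatic CTF estimation over a tilt-series
#'
#' Convenience pipeline: for every image of a stack, estimate a centre
#' defocus from near-axis tiles, build the tilt-corrected power spectrum and
#' run the astigmatic fit.
#'
#' @param stack 3D array (nx, ny, ntilt) or list of matrices.
#' @param geoms list of [tilt_geometry()], one per tilt.
#' @param params0 microscope constants. @param search defocus grid.
#' @param tile_size px. @param pixel_size Angstrom/px.
#' @return data frame: `tilt_index, tilt_angle, defocus1, defocus2,
#'   astig_angle, fit_score, fit_resolution_A`.
#' @export
ctf_fit_tilt_series <- function(stack, geoms, params0, search,
                                tile_size = 128, pixel_size = 1) {
  imgs <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  rows <- lapply(seq_along(imgs), function(i) {
    g <- geoms[[i]]
    hint <- estimate_center_defocus(imgs[[i]], g, params0, search,
                                    tile_size, pixel_size)
    sp <- tilted_power_spectrum(imgs[[i]], g, tile_size, hint, pixel_size)
    fit <- fit_astigmatic_ctf(sp, search, params0)
    data.frame(tilt_index = i, tilt_angle = g$tilt_angle,
               defocus1 = fit$params$defocus1, defocus2 = fit$params$defocus2,
               astig_angle = fit$params$astig_angle,
               fit_score = fit$fit_score,
               fit_resolution_A = fit$fit_resolution_A)
  })
  do.call(rbind, rows)
}
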