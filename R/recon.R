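# Scoring, score-driven exposure weights, weighted Fourier-insertion
# reconstruction and Fourier shell correlation.

proj_rotation <- function(row) {
  tilt_rotation(row$theta, row$axis_angle) %*%
    euler_zyz(row$e1_deg, row$e2_deg, row$e3_deg)
}

# Band annulus indices on the centred box grid, band in Angstrom c(lo_res,
# hi_res) e.g. c(20, 8).
band_mask <- function(box, pixel_size, band) {
  f <- kgrid(box) / (box * pixel_size)
  fr <- sqrt(outer(f^2, f^2, `+`))
  which(fr >= 1 / band[1] & fr <= 1 / band[2])
}

#' Score particle projections against a reference map
#'
#' Each extracted projection is compared to the CTF-modulated central-slice
#' reprojection of the reference at its combined orientation (tilt transform
#' composed with the particle pose) and matching sub-pixel shift. The score
#' is the absolute value of the normalized band-limited cross-correlation:
#' the absolute value makes the score insensitive to contrast inversion and
#' matches how the scores are consumed by the exposure weighting.
#'
#' @param stack `box x box x n` projection array (`[x, y]` layout).
#' @param reference 3D reference map (same box and pixel size).
#' @param meta projection table from [extract_particle_projections()] /
#'   [simulate_particle_dataset()] (orientations, offsets, defocus).
#' @param band scoring resolution band in Angstrom, `c(low_res, high_res)`;
#'   decoupling the scoring band from the frequencies being reconstructed
#'   limits overfitting.
#' @param pixel_size Angstrom/px.
#' @return Numeric vector of scores in `[0, 1]`, one per projection.
#' @export
score_projections <- function(stack, reference, meta, band = c(20, 8),
                              pixel_size) {
  box <- dim(stack)[1]
  if (band[1] <= band[2]) stop_bisectr("band must be c(low_res, high_res) with low > high")
  sel <- band_mask(box, pixel_size, band)
  if (length(sel) == 0) stop_bisectr("empty scoring band")
  ref_hat <- ref_transform(reference)
  vapply(seq_len(dim(stack)[3]), function(i) {
    row <- meta[i, ]
    d <- image_to_slice(stack[, , i])[sel]
    ctf <- ctf_image(box, ctf_params(row$defocus1, row$defocus2,
                                     row$astig_angle,
                                     pixel_size = pixel_size))
    m <- (extract_slice(ref_hat, proj_rotation(row)) * ctf *
            phase_ramp(box, row$dx_px, row$dy_px))[sel]
    den <- sqrt(sum(Mod(d)^2) * sum(Mod(m)^2))
    if (den == 0) return(0)
    Mod(sum(d * Conj(m))) / den
  }, numeric(1))
}

#' Derive per-tilt exposure weights from similarity scores
#'
#' Mean scores per tilt are converted into isotropic B factors relative to
#' the best tilt, `B_i = c * (max_j s_j - s_i)`, giving frequency weights
#' `w_i(f) = exp(-B_i f^2 / 4)`. The best tilt is never attenuated and no
#' weight exceeds 1, so the filter only down-weights tilts whose data
#' empirically agree less with the reference -- no knowledge of the tilt
#' scheme or exposure is needed.
#'
#' @param scores numeric vector of per-projection scores.
#' @param tilt_index integer vector parallel to `scores`.
#' @param c_A2 conversion constant, Angstrom^2 of B per unit of lost mean
#'   score, or `"log"` for the self-calibrated conversion
#'   `B_i = (4 / f0^2) * log(s_max / s_i)` with `f0` the centre of the
#'   scoring band: in the low-SNR regime the band-limited score is
#'   proportional to signal amplitude, so the log ratio reads the
#'   attenuation directly and no free constant is needed.
#' @param band scoring band (Angstrom, `c(low, high)`) used by the
#'   `"log"` conversion.
#' @return `exposure_weights` object: `tilt_index`, `mean_score`, `B_A2`,
#'   `c_A2`.
#' @export
derive_exposure_weights <- function(scores, tilt_index, c_A2 = 100,
                                    band = c(20, 8)) {
  if (length(scores) != length(tilt_index) || length(scores) == 0) {
    stop_bisectr("need one tilt index per score")
  }
  s <- tapply(scores, tilt_index, mean)
  idx <- as.integer(names(s))
  s_num <- as.numeric(s)
  if (identical(c_A2, "log")) {
    f0 <- mean(1 / band)
    s_pos <- pmax(s_num, max(s_num) * 1e-3)
    B <- (4 / f0^2) * log(max(s_pos) / s_pos)
  } else {
    B <- c_A2 * (max(s_num) - s_num)
  }
  structure(list(tilt_index = idx, mean_score = s_num,
                 B_A2 = B, c_A2 = c_A2),
            class = "exposure_weights")
}

#' @export
print.exposure_weights <- function(x, ...) {
  cat(sprintf("exposure weights over %d tilts: B in [%.1f, %.1f] A^2 (c = %s)\n",
              length(x$B_A2), min(x$B_A2), max(x$B_A2), as.character(x$c_A2)))
  invisible(x)
}

# B factor for given tilt indices (0 when weights are NULL).
weights_B <- function(weights, tilt_index) {
  if (is.null(weights)) return(rep(0, length(tilt_index)))
  B <- weights$B_A2[match(tilt_index, weights$tilt_index)]
  ifelse(is.na(B), 0, B)
}

#' Per-tilt spectral contribution surface
#'
#' Fraction of the total reconstruction weight contributed by each tilt as
#' a function of spatial frequency (rows = tilts in acquisition order,
#' columns = frequency shells): the weighted analogue of a cumulative
#' exposure plot. High frequencies end up dominated by the early, low-tilt
#' exposures.
#'
#' @param weights an [derive_exposure_weights()] object.
#' @param freq vector of spatial frequencies, 1/Angstrom.
#' @export
spectral_contribution <- function(weights, freq) {
  w <- vapply(weights$B_A2, function(B) exp(-B * freq^2 / 4),
              numeric(length(freq)))
  w <- t(w)                     # tilts x freq
  sweep(w, 2, colSums(w), "/")
}

#' Exposure-weighted direct Fourier reconstruction
#'
#' Inserts every projection's centred FT into the 3D Fourier volume at its
#' combined orientation with trilinear spreading, accumulating
#' `w * CTF * data` in the numerator and `w * CTF^2` in the denominator
#' (a Wiener constant of `wiener_frac` times the per-shell mean of the
#' denominator regularizes the division). Two half-maps are built from the
#' odd/even split of particle ids, so the halves share no particle.
#'
#' @param stack,meta projections and their table (see
#'   [extract_particle_projections()]).
#' @param pixel_size Angstrom/px.
#' @param weights optional [derive_exposure_weights()]; `NULL` = unweighted.
#' @param wiener_frac Wiener constant as a fraction of the shell-mean
#'   denominator.
#' @param pad Fourier oversampling factor of the insertion grid (2 keeps
#'   trilinear gridding error negligible).
#' @return list: `map`, `half1`, `half2` (arrays with `pixel_size`
#'   attribute), `denominator` diagnostics.
#' @export
weighted_reconstruct <- function(stack, meta, pixel_size, weights = NULL,
                                 wiener_frac = 0.1, pad = 2) {
  box <- dim(stack)[1]
  n_proj <- dim(stack)[3]
  if (n_proj == 0 || nrow(meta) != n_proj) stop_bisectr("empty or mismatched stack")
  nb <- box * pad                       # oversampled insertion grid
  k <- kgrid(box)
  kx <- rep(k, times = box); ky <- rep(k, each = box)
  f <- k / (box * pixel_size)
  f2 <- outer(f^2, f^2, `+`)
  ctr <- floor(nb / 2) + 1
  nvox <- nb^3
  accum <- list()
  for (h in c("h1", "h2")) {
    accum[[h]] <- list(re = numeric(nvox), im = numeric(nvox), den = numeric(nvox))
  }
  B_all <- weights_B(weights, meta$tilt_index)
  for (i in seq_len(n_proj)) {
    row <- meta[i, ]
    R <- proj_rotation(row)
    # undo the sub-pixel extraction offset so the particle sits at the
    # box centre before insertion
    d <- image_to_slice(stack[, , i]) * phase_ramp(box, -row$dx_px, -row$dy_px)
    ctf <- ctf_image(box, ctf_params(row$defocus1, row$defocus2,
                                     row$astig_angle, pixel_size = pixel_size))
    w <- exp(-B_all[i] * f2 / 4)
    val <- as.vector(w * ctf * d)
    wt <- as.vector(w * ctf^2)
    q <- t(R) %*% rbind(kx, ky, 0) * pad
    xi <- q[1, ] + ctr; yi <- q[2, ] + ctr; zi <- q[3, ] + ctr
    ok <- xi >= 1 & xi <= nb - 1e-9 & yi >= 1 & yi <= nb - 1e-9 &
      zi >= 1 & zi <= nb - 1e-9
    xi <- xi[ok]; yi <- yi[ok]; zi <- zi[ok]
    val <- val[ok]; wt <- wt[ok]
    x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
    fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
    base <- x0 + (y0 - 1) * nb + (z0 - 1) * nb * nb
    half <- if (row$particle_id %% 2 == 1) "h1" else "h2"
    a <- accum[[half]]
    # all 8 trilinear corners in one accumulation pass
    idx_all <- numeric(0); w_all <- numeric(0)
    for (corner in 0:7) {
      dx <- corner %% 2; dy <- (corner %/% 2) %% 2; dzc <- corner %/% 4
      wcorn <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dzc) fz else 1 - fz)
      idx_all <- c(idx_all, base + dx + dy * nb + dzc * nb * nb)
      w_all <- c(w_all, wcorn)
    }
    vr <- rep(Re(val), 8) * w_all
    vi <- rep(Im(val), 8) * w_all
    vw <- rep(wt, 8) * w_all
    contrib <- rowsum(cbind(vr, vi, vw), idx_all, reorder = FALSE)
    tgt <- as.integer(rownames(contrib))
    a$re[tgt] <- a$re[tgt] + contrib[, 1]
    a$im[tgt] <- a$im[tgt] + contrib[, 2]
    a$den[tgt] <- a$den[tgt] + contrib[, 3]
    accum[[half]] <- a
  }
  finish <- function(re, im, den) {
    if (max(den) == 0) {
      m <- array(0, c(box, box, box))
      attr(m, "pixel_size") <- pixel_size
      return(m)
    }
    num <- array(complex(real = re, imaginary = im), c(nb, nb, nb))
    den <- array(den, c(nb, nb, nb))
    sh <- shell_index(dim(den))
    nsh <- floor(nb / 2)
    lam <- wiener_frac * shell_mean(den, sh, nsh)
    lam[is.na(lam) | lam <= 0] <- max(den) * 1e-6
    lam_vox <- array(lam[pmin(sh, nsh)], c(nb, nb, nb))
    big <- Re(ifftc(num / (den + lam_vox + max(den) * 1e-9))) * pad^3
    off <- floor((nb - box) / 2)
    m <- big[off + seq_len(box), off + seq_len(box), off + seq_len(box)]
    # gridding correction: trilinear spreading multiplies real space by a
    # separable sinc^2 envelope, divided out over the cropped box
    snc <- function(x) ifelse(x == 0, 1, sin(pi * x / nb) / (pi * x / nb))
    e1 <- snc(kgrid(box))^2
    m <- m / outer(outer(e1, e1), e1)
    attr(m, "pixel_size") <- pixel_size
    m
  }
  h1 <- accum$h1; h2 <- accum$h2
  list(map = finish(h1$re + h2$re, h1$im + h2$im, h1$den + h2$den),
       half1 = finish(h1$re, h1$im, h1$den),
       half2 = finish(h2$re, h2$im, h2$den),
       denominator = h1$den + h2$den)
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalized correlation of the centred FTs; resolution is read
#' at the first downward crossing of `threshold` (linear interpolation
#' between shells; the 0.143 criterion is the half-map convention). If a
#' mask is supplied both masked and unmasked curves are computed.
#'
#' @param map_a,map_b equal-dimension arrays.
#' @param pixel_size Angstrom/voxel (defaults to the maps' attribute).
#' @param mask optional real-space mask in `[0, 1]`.
#' @param threshold resolution criterion (default 0.143).
#' @return `fsc_curve`: list with `freq` (1/Angstrom), `fsc`,
#'   `resolution_A`, and `masked` (nested curve) when a mask is given.
#' @export
compute_fsc <- function(map_a, map_b, pixel_size = NULL, mask = NULL,
                        threshold = 0.143) {
  if (!all(dim(map_a) == dim(map_b))) stop_bisectr("map dimensions differ")
  if (all(map_a == 0) || all(map_b == 0)) stop_bisectr("all-zero map")
  pixel_size <- pixel_size %||% attr(map_a, "pixel_size") %||% 1
  curve <- function(a, b) {
    fa <- fftc(a); fb <- fftc(b)
    sh <- shell_index(dim(a))
    nsh <- floor(dim(a)[1] / 2)
    num <- shell_sum(Re(fa * Conj(fb)), sh, nsh)
    da <- shell_sum(Mod(fa)^2, sh, nsh)
    db <- shell_sum(Mod(fb)^2, sh, nsh)
    fsc <- num / sqrt(pmax(da * db, .Machine$double.xmin))
    freq <- (seq_len(nsh) - 1) / (dim(a)[1] * pixel_size)
    res <- resolution_at(freq, fsc, threshold)
    structure(list(freq = freq, fsc = fsc, resolution_A = res,
                   threshold = threshold), class = "fsc_curve")
  }
  out <- curve(map_a, map_b)
  if (!is.null(mask)) out$masked <- curve(map_a * mask, map_b * mask)
  out
}

resolution_at <- function(freq, fsc, threshold) {
  below <- which(fsc < threshold & seq_along(fsc) > 1)
  if (length(below) == 0) return(1 / freq[length(freq)])  # never crosses
  i <- below[1]
  f0 <- freq[i - 1]; f1 <- freq[i]
  v0 <- fsc[i - 1]; v1 <- fsc[i]
  fc <- f0 + (v0 - threshold) / (v0 - v1) * (f1 - f0)
  1 / fc
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("FSC over %d shells; resolution at %.3f: %.2f A\n",
              length(x$freq), x$threshold, x$resolution_A))
  invisible(x)
}
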