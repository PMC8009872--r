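# Constrained rigid-body refinement: one pose per particle, per-tilt
# orientations slaved to it through the tilt geometry.

# Mean band-limited |NCC| of one particle's projections against reference
# reprojections for pose (e1, e2, e3, sx_um, sy_um). The in-plane shift is
# a 2D offset in the untilted specimen plane; its projection through each
# tilt gives the per-tilt image shift.
# Geodesic angle (degrees) between two ZYZ Euler orientations; the right
# metric near the e2 = 0 gimbal line where e1 and e3 trade off.
rotation_distance_deg <- function(e_a, e_b) {
  R <- t(euler_zyz(e_a[1], e_a[2], e_a[3])) %*%
    euler_zyz(e_b[1], e_b[2], e_b[3])
  rad2deg(acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)))
}

particle_score <- function(par, rows, data_slices, ctfs, ref_hat, sel, box,
                           pixel_size) {
  total <- 0
  for (j in seq_along(rows)) {
    row <- rows[[j]]
    Rt <- tilt_rotation(row$theta, row$axis_angle)
    R <- Rt %*% euler_zyz(par[1], par[2], par[3])
    dpx <- (Rt %*% c(par[4], par[5], 0))[1:2] * 1e4 / pixel_size
    m <- (extract_slice(ref_hat, R) * ctfs[[j]] *
            phase_ramp(box, row$dx_px + dpx[1], row$dy_px + dpx[2]))[sel]
    d <- data_slices[[j]]
    den <- sqrt(sum(Mod(d)^2) * sum(Mod(m)^2))
    if (den > 0) total <- total + Mod(sum(d * Conj(m))) / den
  }
  total / length(rows)
}

#' Constrained rigid-body refinement of particle poses
#'
#' Refines, per particle, a single rigid body (three ZYZ Euler angles plus
#' a 2D in-plane shift in the untilted specimen plane) by maximizing the
#' sum over tilts of the band-limited absolute cross-correlation between
#' the particle's extracted projections and CTF-modulated reprojections of
#' the reference; every tilt's orientation is derived from the one particle
#' pose through the tilt geometry, which is what constrains the problem.
#' Local refinement only: excursions beyond `search` are reverted and the
#' particle flagged, as are refinements that fail to improve the score.
#'
#' @param stack,meta projections and table (see
#'   [extract_particle_projections()]); `meta` must carry initial
#'   orientations and per-projection defocus.
#' @param reference 3D reference map.
#' @param search list `angle` (degrees) and `shift_px` (pixels): search
#'   budget around the initial values.
#' @param band scoring band, Angstrom `c(low, high)`.
#' @param pixel_size Angstrom/px.
#' @param maxit Nelder-Mead iteration budget per band stage.
#' @return list: `particles` (one row per particle: refined
#'   `e1_deg, e2_deg, e3_deg, sx_um, sy_um`, scores, `flagged`),
#'   `meta` (input table with refined orientations substituted).
#' @export
constrained_refine <- function(stack, meta, reference,
                               search = list(angle = 4, shift_px = 4),
                               band = c(20, 8), pixel_size, maxit = 400) {
  box <- dim(stack)[1]
  # coarse-to-fine band schedule: the high-resolution score landscape is
  # rugged once angle and shift are jointly off; a smooth low-resolution
  # pass brings the pose into the fine band's convergence basin
  coarse <- c(max(2.5 * band[1], 40), 2 * band[2])
  sels <- list(band_mask(box, pixel_size, coarse),
               band_mask(box, pixel_size, band))
  ref_hat <- ref_transform(reference)
  ids <- unique(meta$particle_id)
  shift_budget_um <- search$shift_px * pixel_size / 1e4
  out <- vector("list", length(ids))
  meta_new <- meta
  for (u in seq_along(ids)) {
    rows_idx <- which(meta$particle_id == ids[u])
    rows <- lapply(rows_idx, function(i) meta[i, ])
    slices_full <- lapply(rows_idx, function(i) image_to_slice(stack[, , i]))
    ctfs <- lapply(rows, function(row)
      ctf_image(box, ctf_params(row$defocus1, row$defocus2, row$astig_angle,
                                pixel_size = pixel_size)))
    p0 <- c(rows[[1]]$e1_deg, rows[[1]]$e2_deg, rows[[1]]$e3_deg, 0, 0)
    to_um <- pixel_size / 1e4
    start <- p0
    for (sel in sels) {
      data_slices <- lapply(slices_full, function(sl) sl[sel])
      obj <- function(q) {
        -particle_score(c(q[1:3], q[4:5] * to_um), rows, data_slices, ctfs,
                        ref_hat, sel, box, pixel_size)
      }
      opt <- optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9))
      start <- opt$par
    }
    sel <- sels[[2]]
    data_slices <- lapply(slices_full, function(sl) sl[sel])
    s0 <- particle_score(p0, rows, data_slices, ctfs, ref_hat, sel, box,
                         pixel_size)
    p1 <- c(start[1:3], start[4:5] * to_um)
    s1 <- particle_score(p1, rows, data_slices, ctfs, ref_hat, sel, box,
                         pixel_size)
    over_budget <- rotation_distance_deg(p0[1:3], p1[1:3]) > search$angle ||
      any(abs(p1[4:5]) > shift_budget_um)
    flagged <- over_budget || s1 < s0
    if (flagged) { p1 <- p0; s1 <- s0 }
    out[[u]] <- data.frame(particle_id = ids[u],
                           e1_deg = p1[1], e2_deg = p1[2], e3_deg = p1[3],
                           sx_um = p1[4], sy_um = p1[5],
                           score_before = s0, score_after = s1,
                           flagged = flagged)
    meta_new$e1_deg[rows_idx] <- p1[1]
    meta_new$e2_deg[rows_idx] <- p1[2]
    meta_new$e3_deg[rows_idx] <- p1[3]
    # fold the refined specimen-plane shift into the per-tilt offsets
    for (i in rows_idx) {
      Rt <- tilt_rotation(meta$theta[i], meta$axis_angle[i])
      dpx <- (Rt %*% c(p1[4], p1[5], 0))[1:2] * 1e4 / pixel_size
      meta_new$dx_px[i] <- meta$dx_px[i] + dpx[1]
      meta_new$dy_px[i] <- meta$dy_px[i] + dpx[2]
    }
  }
  list(particles = do.call(rbind, out), meta = meta_new)
}

#' Refine the tilt-series geometry against all its particles
#'
#' Second refinement stage: with particle poses fixed, re-estimates the
#' tilt-axis orientation (and optionally small per-tilt angle offsets) of
#' one tilt-series by maximizing the summed band-limited scores of all its
#' particles. In-plane shifts are deliberately left to tracking/alignment.
#'
#' @param stack,meta projections and table of one tilt-series.
#' @param reference 3D reference map.
#' @param axis_window degrees searched around the current axis angle.
#' @param per_tilt_offsets also refine a small angle offset per tilt.
#' @param offset_window degrees searched per tilt.
#' @inheritParams constrained_refine
#' @return list: `axis_angle_offset` (degrees), `tilt_offsets` (degrees per
#'   tilt or NULL), `score`.
#' @export
refine_tilt_geometry <- function(stack, meta, reference, axis_window = 2,
                                 per_tilt_offsets = FALSE, offset_window = 1,
                                 band = c(20, 8), pixel_size) {
  box <- dim(stack)[1]
  sel <- band_mask(box, pixel_size, band)
  ref_hat <- ref_transform(reference)
  data_slices <- lapply(seq_len(dim(stack)[3]),
                        function(i) image_to_slice(stack[, , i])[sel])
  ctfs <- lapply(seq_len(nrow(meta)), function(i)
    ctf_image(box, ctf_params(meta$defocus1[i], meta$defocus2[i],
                              meta$astig_angle[i], pixel_size = pixel_size)))
  total_score <- function(d_axis, d_tilt = NULL) {
    s <- 0
    for (i in seq_len(nrow(meta))) {
      row <- meta[i, ]
      dth <- if (is.null(d_tilt)) 0 else d_tilt[row$tilt_index]
      R <- tilt_rotation(row$theta + dth, row$axis_angle + d_axis) %*%
        euler_zyz(row$e1_deg, row$e2_deg, row$e3_deg)
      m <- (extract_slice(ref_hat, R) * ctfs[[i]] *
              phase_ramp(box, row$dx_px, row$dy_px))[sel]
      d <- data_slices[[i]]
      den <- sqrt(sum(Mod(d)^2) * sum(Mod(m)^2))
      if (den > 0) s <- s + Mod(sum(d * Conj(m))) / den
    }
    s
  }
  opt <- optimize(function(a) -total_score(a), c(-axis_window, axis_window),
                  tol = 0.02)
  d_axis <- opt$minimum
  tilt_offsets <- NULL
  if (per_tilt_offsets) {
    tilts <- sort(unique(meta$tilt_index))
    tilt_offsets <- setNames(rep(0, length(tilts)), tilts)
    for (t in tilts) {
      sub <- which(meta$tilt_index == t)
      score_t <- function(dth) {
        s <- 0
        for (i in sub) {
          row <- meta[i, ]
          R <- tilt_rotation(row$theta + dth, row$axis_angle + d_axis) %*%
            euler_zyz(row$e1_deg, row$e2_deg, row$e3_deg)
          m <- (extract_slice(ref_hat, R) * ctfs[[i]] *
                  phase_ramp(box, row$dx_px, row$dy_px))[sel]
          d <- data_slices[[i]]
          den <- sqrt(sum(Mod(d)^2) * sum(Mod(m)^2))
          if (den > 0) s <- s + Mod(sum(d * Conj(m))) / den
        }
        s
      }
      tilt_offsets[as.character(t)] <-
        optimize(function(a) -score_t(a), c(-offset_window, offset_window),
                 tol = 0.02)$minimum
    }
  }
  list(axis_angle_offset = d_axis, tilt_offsets = tilt_offsets,
       score = total_score(d_axis, if (per_tilt_offsets)
         tilt_offsets[as.character(sort(unique(meta$tilt_index)))] else NULL))
}
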