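# Seeded specimen scene and virtual stage for closed-loop acquisition
# simulation. All randomness is drawn from the R session RNG; callers seed
# it once per session, which makes every downstream draw reproducible.

#' Construct a synthetic grid scene
#'
#' Builds a deterministic (seeded) specimen model around one tracking
#' position: a lattice of target holes (regions of interest) with random
#' per-hole height offsets emulating grid topography, a set of gold-bead
#' fiducials clustered around the tracking area, and a smooth background
#' texture field sampled by the renderer. Height offsets of the order of
#' 0.1 micrometre are enough to defeat a planar targeting model, which is
#' the regime this scene emulates.
#'
#' @param config list merged over [grid_scene_config()].
#' @param seed integer seed; the same seed reproduces the scene exactly.
#' @return Object of class `grid_scene`: list with `rois` (data frame:
#'   `id, x_um, y_um, z_um, bis_x, bis_y`), `fiducials` (matrix, micrometres),
#'   `texture` (matrix), `texture_spacing_A`, `config`, `seed`.
#' @export
make_grid_scene <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(grid_scene_config(), config)
  set.seed(as.integer(seed))
  lat <- cfg$lattice
  if (length(lat) != 2 || any(lat < 1)) stop_bisectr("lattice must be two positive counts")
  ix <- seq_len(lat[1]) - (lat[1] + 1) / 2
  iy <- seq_len(lat[2]) - (lat[2] + 1) / 2
  grid <- expand.grid(x = ix * cfg$pitch_um, y = iy * cfg$pitch_um)
  z <- rnorm(nrow(grid), 0, cfg$topo_sigma_um)
  z <- pmin(pmax(z, -cfg$topo_max_um), cfg$topo_max_um)
  if (cfg$topo_sigma_um == 0) z <- rep(0, nrow(grid))
  rois <- data.frame(id = sprintf("roi_%02d", seq_len(nrow(grid))),
                     x_um = grid$x, y_um = grid$y, z_um = z,
                     bis_x = grid$x, bis_y = grid$y,
                     stringsAsFactors = FALSE)
  # fiducials: a dense central cluster (visible at high mag) plus a wider
  # spread covering the low-mag field of view
  n_in <- cfg$n_fiducials_center; n_out <- cfg$n_fiducials_wide
  fid <- rbind(
    cbind(runif(n_in, -0.11, 0.11), runif(n_in, -0.11, 0.11)),
    cbind(runif(n_out, -0.55, 0.55), runif(n_out, -0.55, 0.55)))
  fid <- cbind(fid, runif(n_in + n_out, -cfg$ice_half_thickness_um,
                          cfg$ice_half_thickness_um))
  colnames(fid) <- c("x_um", "y_um", "z_um")
  # smooth background texture over specimen coordinates
  set.seed(derive_seed(seed, 2L))
  n <- cfg$texture_n
  white <- matrix(rnorm(n * n), n)
  f2 <- outer(freq_fft(n)^2, freq_fft(n)^2, `+`)
  tex <- Re(fft(fft(white) * exp(-f2 / (2 * 0.04^2)), inverse = TRUE)) / (n * n)
  tex <- (tex - mean(tex)) / sd(tex)
  structure(list(rois = rois, fiducials = fid, texture = tex,
                 texture_spacing_A = cfg$texture_extent_um * 1e4 / n,
                 config = cfg, seed = seed),
            class = "grid_scene")
}

#' Default scene parameters
#'
#' Lattice and pitch follow the 5 x 5 pattern of holes on an R1.2/1.3-style
#' grid (2.5 um pitch, about 7.1 um maximal image-shift distance);
#' topography scatter defaults to 0.1 um, the scale at which planar
#' targeting visibly breaks down.
#' @export
grid_scene_config <- function() {
  list(lattice = c(5, 5), pitch_um = 2.5,
       topo_sigma_um = 0.1, topo_max_um = 0.5,
       n_fiducials_center = 30, n_fiducials_wide = 50,
       ice_half_thickness_um = 0.01,
       bead_sigma_A = 100, bead_amp = 6,
       texture_n = 512, texture_extent_um = 5.12)
}

#' Create a virtual microscope stage
#'
#' Mutable stage model (an environment): mechanical tilting draws fresh
#' in-plane jitter (Gaussian, `in_plane_sigma_nm` per axis, accumulating
#' across moves as on a real goniometer), while applied beam-image shift is
#' exact and persists. A fixed eucentricity offset displaces the tracking
#' plane along the beam for the whole session.
#'
#' @param in_plane_sigma_nm per-axis jitter of a mechanical move, nm.
#'   Mechanical stages are no better than ~200 nm in plane.
#' @param eucentricity_offset_um height error of the tracking area.
#' @return Environment of class `virtual_stage`.
#' @export
virtual_stage <- function(in_plane_sigma_nm = 200, eucentricity_offset_um = 0.25) {
  st <- new.env(parent = emptyenv())
  st$theta <- 0
  st$pose_err_um <- c(0, 0)
  st$applied_is_um <- c(0, 0)
  st$sigma_um <- in_plane_sigma_nm / 1000
  st$z_track_um <- eucentricity_offset_um
  class(st) <- "virtual_stage"
  st
}

#' @rdname virtual_stage
#' @param stage a `virtual_stage`.
#' @param theta target tilt angle, degrees.
#' @export
stage_tilt <- function(stage, theta) {
  stage$theta <- theta
  stage$pose_err_um <- stage$pose_err_um + rnorm(2, 0, stage$sigma_um)
  invisible(stage)
}

#' @rdname virtual_stage
#' @param delta_um incremental image-plane shift, micrometres.
#' @export
apply_image_shift <- function(stage, delta_um) {
  stage$applied_is_um <- stage$applied_is_um + delta_um
  invisible(stage)
}

# In-image displacement (um) of the tracking-area content relative to the
# nominal (error-free) view: stage jitter foreshortened perpendicular to the
# axis, plus the eucentric height term, plus applied image shift (the
# correction convention is "applying delta moves the content by delta", so
# tracking corrections are the negated measured shifts).
content_shift_um <- function(stage) {
  ct <- cos(deg2rad(stage$theta)); st_ <- sin(deg2rad(stage$theta))
  c(stage$pose_err_um[1] + stage$applied_is_um[1],
    stage$pose_err_um[2] * ct + stage$z_track_um * st_ + stage$applied_is_um[2])
}

#' Render the tracking-area view at the current stage pose
#'
#' Projects the scene (background texture and gold-bead fiducials) at the
#' stage's tilt: content perpendicular to the tilt axis is foreshortened by
#' `cos(theta)`, the residual pose error displaces the whole field, and
#' Poisson counting noise at the configured dose is added. The tilt axis
#' runs along image columns (x).
#'
#' @param scene a [make_grid_scene()] scene.
#' @param stage a [virtual_stage()].
#' @param pixel_size Angstrom per pixel of this magnification level.
#' @param n image side, pixels.
#' @param dose_e_per_A2 exposure of this shot; `Inf` disables noise.
#' @param contrast specimen contrast fraction mapping the normalized scene
#'   signal to counts.
#' @return `n x n` numeric matrix of (noisy) counts, mean-subtracted.
#' @export
render_view <- function(scene, stage, pixel_size, n = 128,
                        dose_e_per_A2 = 0.5, contrast = 0.15) {
  ct <- cos(deg2rad(stage$theta)); st_ <- sin(deg2rad(stage$theta))
  sh <- content_shift_um(stage) * 1e4 / pixel_size   # px
  rc <- (n + 1) / 2; cc <- (n + 1) / 2
  u <- rep(seq_len(n) - cc, each = n)
  v <- rep(seq_len(n) - rc, times = n)
  xs <- (u - sh[1]) * pixel_size                      # specimen X, Angstrom
  ys <- (v - sh[2]) * pixel_size / ct                 # specimen Y, Angstrom
  tc <- (nrow(scene$texture) + 1) / 2
  img <- bilinear_interp(scene$texture,
                         ys / scene$texture_spacing_A + tc,
                         xs / scene$texture_spacing_A + tc, fill = 0)
  img <- matrix(img, n, n)
  # beads
  cfg <- scene$config
  sg <- cfg$bead_sigma_A / pixel_size
  rad <- max(2, ceiling(3 * sg))
  for (i in seq_len(nrow(scene$fiducials))) {
    p <- scene$fiducials[i, ]
    ub <- p[1] * 1e4 / pixel_size + sh[1] + cc
    vb <- (p[2] * ct + p[3] * st_) * 1e4 / pixel_size + sh[2] + rc
    if (ub < -rad || ub > n + rad || vb < -rad || vb > n + rad) next
    ccols <- max(1, floor(ub - rad)):min(n, ceiling(ub + rad))
    crows <- max(1, floor(vb - rad)):min(n, ceiling(vb + rad))
    if (!length(ccols) || !length(crows)) next
    g <- cfg$bead_amp * outer(exp(-(crows - vb)^2 / (2 * sg^2)),
                              exp(-(ccols - ub)^2 / (2 * sg^2)))
    img[crows, ccols] <- img[crows, ccols] - g   # beads are dark
  }
  if (is.finite(dose_e_per_A2)) {
    dose_px <- dose_e_per_A2 * pixel_size^2
    lambda <- dose_px * pmax(0.02, 1 + contrast * img / max(1, sd(img)))
    img <- matrix(rpois(n * n, lambda), n, n) / dose_px - 1
  }
  img - mean(img)
}
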