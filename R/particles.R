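# Particle records, synthetic phantom and tilt-series particle simulation.
# Reconstruction-side images (boxes, micrographs) are stored [x, y]: first
# index is the image x coordinate.

#' Analytic test phantom at the ~300 kDa scale
#'
#' A rigid cluster of Gaussian blobs with approximate 3-fold dihedral
#' arrangement, about 70 Angstrom across: two staggered rings of three
#' blobs plus an axial pair. Deterministic, band-limited, and asymmetric
#' enough to define orientation uniquely.
#'
#' @param n box side, voxels. @param pixel_size Angstrom/voxel.
#' @return `n^3` array with attribute `pixel_size`.
#' @export
make_phantom <- function(n = 32, pixel_size = 3) {
  r_ring <- 22; z_off <- 10; sig <- 4.5  # Angstrom; sharp enough to carry
  # spectral power out to half-Nyquist at 3 A/voxel while staying
  # band-limited (FT amplitude ~1e-4 at Nyquist)
  ang1 <- c(0, 120, 240); ang2 <- ang1 + 60
  centers <- rbind(
    cbind(r_ring * cos(deg2rad(ang1)), r_ring * sin(deg2rad(ang1)), z_off),
    cbind(r_ring * cos(deg2rad(ang2)), r_ring * sin(deg2rad(ang2)), -z_off),
    c(0, 0, 16), c(0, 0, -4))
  amps <- c(1, 1, 1, 1, 1, 1, 1.4, 0.8)
  ax <- (kgrid(n)) * pixel_size
  v <- array(0, c(n, n, n))
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(ax - centers[i, 1])^2 / (2 * sig^2))
    gy <- exp(-(ax - centers[i, 2])^2 / (2 * sig^2))
    gz <- exp(-(ax - centers[i, 3])^2 / (2 * sig^2))
    v <- v + amps[i] * outer(outer(gx, gy), gz)
  }
  attr(v, "pixel_size") <- pixel_size
  v
}

#' Assign per-tilt defocus to a particle from its 3D position
#'
#' For tilt `theta` the particle's height along the beam is
#' `z' = -y sin(theta) + z cos(theta)` (tilt-axis frame); converted to
#' Angstrom it is added to both defocus components of that tilt's CTF, so
#' each projection carries the defocus of the particle's actual depth
#' within the tomogram.
#'
#' @param particle list/row with `x_um`, `y_um`, `z_um` (tomogram-centre
#'   frame, micrometres).
#' @param geoms list of [tilt_geometry()], one per tilt.
#' @param per_tilt_ctf list of [ctf_params()], one per tilt.
#' @return data frame: `tilt_index, defocus_offset_A, defocus1, defocus2,
#'   astig_angle`.
#' @export
assign_particle_defocus <- function(particle, geoms, per_tilt_ctf) {
  if (length(geoms) != length(per_tilt_ctf)) {
    stop_bisectr("need one CTF per tilt: %d geometries vs %d CTFs",
                 length(geoms), length(per_tilt_ctf))
  }
  p <- c(particle$x_um, particle$y_um, particle$z_um)
  rows <- lapply(seq_along(geoms), function(i) {
    if (is.null(per_tilt_ctf[[i]])) stop_bisectr("missing CTF for tilt %d", i)
    R <- tilt_rotation(geoms[[i]]$tilt_angle, geoms[[i]]$tilt_axis_angle)
    off_A <- (R %*% p)[3] * 1e4
    ctf <- per_tilt_ctf[[i]]
    data.frame(tilt_index = i, defocus_offset_A = off_A,
               defocus1 = ctf$defocus1 + off_A,
               defocus2 = ctf$defocus2 + off_A,
               astig_angle = ctf$astig_angle)
  })
  do.call(rbind, rows)
}

# Projected image-plane centre (px, [x, y]) of a 3D position at one tilt.
project_center_px <- function(pos_um, geom, pixel_size, image_n) {
  R <- tilt_rotation(geom$tilt_angle, geom$tilt_axis_angle)
  q <- (R %*% pos_um)[1:2] * 1e4 / pixel_size
  A <- matrix(geom$xf[1:4], 2, 2, byrow = TRUE)
  q <- A %*% q + geom$xf[5:6]
  q + floor(image_n / 2) + 1
}

#' Extract per-particle projection boxes from a tilt-series
#'
#' Projects each particle's 3D position through every tilt transform, cuts a
#' `box` pixel window around the rounded centre and records the residual
#' sub-pixel offset. Tilts whose projected centre comes closer than `box/2`
#' to an image edge are marked not visible and skipped; particles visible in
#' no tilt are dropped with a warning.
#'
#' @param stack 3D array `(nx, ny, ntilt)`, `[x, y]` layout, or list.
#' @param geoms list of [tilt_geometry()] per tilt.
#' @param particles data frame: `particle_id, x_um, y_um, z_um,
#'   e1_deg, e2_deg, e3_deg`.
#' @param box box side, px. @param pixel_size Angstrom/px.
#' @return list: `stack` (box x box x nproj), `meta` (data frame with one
#'   row per extracted projection: ids, tilt, angles, centre, sub-pixel
#'   offset).
#' @export
extract_particle_projections <- function(stack, geoms, particles, box,
                                         pixel_size) {
  imgs <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  n_img <- nrow(imgs[[1]])
  half <- box / 2
  meta <- list(); boxes <- list(); k <- 0L
  for (pi_ in seq_len(nrow(particles))) {
    p <- particles[pi_, ]
    seen <- 0L
    for (ti in seq_along(imgs)) {
      ctr <- project_center_px(c(p$x_um, p$y_um, p$z_um), geoms[[ti]],
                               pixel_size, n_img)
      c0 <- round(ctr)
      if (any(c0 - half < 1) || any(c0 + half - 1 > n_img)) next
      k <- k + 1L; seen <- seen + 1L
      xr <- (c0[1] - half):(c0[1] + half - 1)
      yr <- (c0[2] - half):(c0[2] + half - 1)
      boxes[[k]] <- imgs[[ti]][xr, yr]
      meta[[k]] <- data.frame(
        particle_id = p$particle_id, tilt_index = ti,
        theta = geoms[[ti]]$tilt_angle,
        axis_angle = geoms[[ti]]$tilt_axis_angle,
        e1_deg = p$e1_deg, e2_deg = p$e2_deg, e3_deg = p$e3_deg,
        x_um = p$x_um, y_um = p$y_um, z_um = p$z_um,
        center_x = ctr[1], center_y = ctr[2],
        dx_px = ctr[1] - c0[1], dy_px = ctr[2] - c0[2])
    }
    if (seen == 0L) {
      warning(sprintf("particle %s visible in no tilt; dropped",
                      as.character(p$particle_id)), call. = FALSE)
    }
  }
  if (k == 0L) stop_bisectr("no projections extracted")
  list(stack = array(unlist(boxes), c(box, box, k)),
       meta = do.call(rbind, meta))
}

#' Simulate a particle tilt-series dataset with dose-dependent damage
#'
#' Renders synthetic tilt-series micrographs containing projections of
#' [make_phantom()] copies at random positions and orientations, each
#' modulated by a per-tilt astigmatic CTF evaluated at the particle's depth
#' and attenuated by a cumulative-dose B factor
#' `exp(-B_dose f^2 / 4)`, `B_dose = dose_b_slope * accumulated dose` --
#' the radiation-damage model that makes later tilts carry less
#' high-frequency signal. Gaussian noise of constant standard deviation is
#' added, so the per-projection SNR decays with accumulated dose. Particle
#' projections are then re-extracted from the rendered micrographs through
#' [extract_particle_projections()], and true per-projection defocus is
#' assigned from particle depth.
#'
#' @param n_particles total particles (split over `n_series` series).
#' @param scheme [tilt_scheme][generate_grouped_dose_symmetric] providing
#'   acquisition order and dose.
#' @param n_series number of tilt-series (tomograms).
#' @param box box side, px. @param pixel_size Angstrom/px.
#' @param image_n micrograph side, px.
#' @param defocus_um_range per-series mean defocus range (micrometres).
#' @param astig_A astigmatism magnitude scale, Angstrom.
#' @param axis_angle tilt-axis orientation of all series, degrees.
#' @param dose_b_slope A^2 of damage B factor per accumulated e-/A^2. The
#'   default 12 matches the canonical critical-exposure curve at the 10 A
#'   scale (amplitude halves by ~15 e-/A^2 there).
#' @param noise_sd Gaussian noise sd relative to unit phantom contrast.
#' @param seed integer.
#' @return list: `stack`, `meta` (with assigned defocus columns), `truth`
#'   (particle table), `geoms`, `ctfs` (per series x tilt), `phantom`,
#'   `scheme`, `pixel_size`.
#' @export
simulate_particle_dataset <- function(n_particles = 100, scheme,
                                      n_series = 4, box = 32, pixel_size = 3,
                                      image_n = 384,
                                      defocus_um_range = c(1.5, 2.5),
                                      astig_A = 300, axis_angle = 0,
                                      dose_b_slope = 12, noise_sd = 1.2,
                                      seed = 1) {
  set.seed(as.integer(seed))
  phantom <- make_phantom(box, pixel_size)
  ph_hat <- ref_transform(phantom)
  angles <- scheme$angles
  cum_dose <- accumulated_dose(scheme)
  n_t <- length(angles)
  per_series <- ceiling(n_particles / n_series)
  f <- kgrid(box) / (box * pixel_size)
  f2 <- outer(f^2, f^2, `+`)
  half_field_um <- (image_n / 2 - box) * pixel_size / 1e4

  all_meta <- list(); all_boxes <- list(); truth <- list(); ctfs_all <- list()
  geoms_all <- list()
  pid0 <- 0L
  for (s in seq_len(n_series)) {
    n_p <- min(per_series, n_particles - pid0)
    geoms <- lapply(angles, function(th) tilt_geometry(axis_angle, th))
    base_dz <- runif(1, defocus_um_range[1], defocus_um_range[2]) * 1e4
    ctfs <- lapply(seq_len(n_t), function(i) {
      ast <- abs(rnorm(1, astig_A, astig_A / 3))
      ctf_params(base_dz + ast / 2, base_dz - ast / 2,
                 astig_angle = runif(1, -90, 90), pixel_size = pixel_size)
    })
    # positions: inside the field at all tilts (|y'| shrinks with tilt, so
    # the zero-tilt footprint bounds visibility); thin slab in z
    parts <- data.frame(
      particle_id = pid0 + seq_len(n_p),
      x_um = runif(n_p, -half_field_um, half_field_um),
      y_um = runif(n_p, -half_field_um * 0.8, half_field_um * 0.8),
      z_um = runif(n_p, -0.04, 0.04),
      e1_deg = runif(n_p, -180, 180),
      e2_deg = rad2deg(acos(runif(n_p, -1, 1))),
      e3_deg = runif(n_p, -180, 180),
      tilt_series_id = s)
    imgs <- vector("list", n_t)
    for (ti in seq_len(n_t)) {
      canvas <- matrix(rnorm(image_n^2, 0, noise_sd), image_n)
      damp <- exp(-dose_b_slope * cum_dose[ti] * f2 / 4)
      for (pi_ in seq_len(n_p)) {
        p <- parts[pi_, ]
        pos <- c(p$x_um, p$y_um, p$z_um)
        ctr <- project_center_px(pos, geoms[[ti]], pixel_size, image_n)
        c0 <- round(ctr)
        if (any(c0 - box / 2 < 1) || any(c0 + box / 2 - 1 > image_n)) next
        R <- tilt_rotation(angles[ti], axis_angle) %*%
          euler_zyz(p$e1_deg, p$e2_deg, p$e3_deg)
        off_A <- (tilt_rotation(angles[ti], axis_angle) %*% pos)[3] * 1e4
        ctf <- ctf_image(box, ctfs[[ti]], defocus_offset = off_A)
        sl <- extract_slice(ph_hat, R) * ctf * damp *
          phase_ramp(box, ctr[1] - c0[1], ctr[2] - c0[2])
        proj <- slice_to_image(sl)
        xr <- (c0[1] - box / 2):(c0[1] + box / 2 - 1)
        yr <- (c0[2] - box / 2):(c0[2] + box / 2 - 1)
        canvas[xr, yr] <- canvas[xr, yr] + proj
      }
      imgs[[ti]] <- canvas
    }
    ex <- extract_particle_projections(imgs, geoms, parts, box, pixel_size)
    # per-projection defocus from particle depth
    dz <- do.call(rbind, lapply(seq_len(nrow(parts)), function(i) {
      d <- assign_particle_defocus(parts[i, ], geoms, ctfs)
      d$particle_id <- parts$particle_id[i]
      d
    }))
    m <- merge(ex$meta, dz, by = c("particle_id", "tilt_index"), sort = FALSE)
    m <- m[order(m$particle_id, m$tilt_index), ]
    m$tilt_series_id <- s
    m$cum_dose <- cum_dose[m$tilt_index]
    all_meta[[s]] <- m
    all_boxes[[s]] <- ex$stack
    truth[[s]] <- parts
    ctfs_all[[s]] <- ctfs
    geoms_all[[s]] <- geoms
    pid0 <- pid0 + n_p
  }
  meta <- do.call(rbind, all_meta)
  stack <- array(unlist(all_boxes), c(box, box, nrow(meta)))
  list(stack = stack, meta = meta, truth = do.call(rbind, truth),
       geoms = geoms_all, ctfs = ctfs_all, phantom = phantom,
       scheme = scheme, pixel_size = pixel_size)
}
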