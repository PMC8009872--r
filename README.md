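# bisectr

Desk-scale toolkit for **beam-image-shift multi-target cryo-electron
tomography acquisition** and **constrained single-particle-style processing
of tilt-series**, written for method developers and acquisition engineers
who want the computational core of a multi-target tilt-series pipeline —
geometry, control loop, CTF and reconstruction — in a form that runs and
tests on a laptop, against a seeded virtual stage instead of a microscope.

## What it implements

Navigating between targets with beam-image shift (BIS) multiplies the
number of regions of interest (ROIs) collected per slow mechanical stage
movement, but only if targeting survives tilting. A target at in-plane
offset $y$ and height $z$ above the plane of rotation moves, at stage tilt
$\theta$, to

$$y' = y\cos\theta + z\sin\theta, \qquad z' = -y\sin\theta + z\cos\theta,$$

so each ROI needs its own eucentric-height fit $(y_0, z_0)$, estimated by
linear least squares from its tracked positions and refined with every
tilt. The package provides:

* grouped dose-symmetric tilt-scheme generation/validation and dose
  bookkeeping (`generate_grouped_dose_symmetric`, `validate_scheme`,
  `accumulated_dose`), with the 41-tilt ±60° and 25-tilt ±36° reference
  sequences bundled as data;
* rotation geometry and per-ROI eucentric fitting
  (`rotate_point_about_tilt_axis`, `fit_eucentric`,
  `predict_roi_correction`);
* iterative two-level tracking on cosine-stretched, band-passed images
  against the series' first image (`cosine_stretch`, `measure_shift`,
  `iterative_track`);
* a seeded closed-loop virtual stage and session controller with
  ground-truth error logging (`make_grid_scene`, `virtual_stage`,
  `run_bisect_session`, `summarize_session`);
* per-tilt astigmatic CTF estimation on tilted micrographs via a
  tilt-corrected tiled power spectrum (`synth_tilted_micrograph`,
  `tilted_power_spectrum`, `fit_astigmatic_ctf`);
* particle-level reconstruction from raw tilt-series projections:
  per-particle defocus from position (`assign_particle_defocus`),
  extraction (`extract_particle_projections`), |CC| scoring
  (`score_projections`), score-driven per-tilt exposure weights
  (`derive_exposure_weights`, $w_i(f) = e^{-B_i f^2/4}$), exposure-weighted
  direct Fourier reconstruction with half-maps (`weighted_reconstruct`),
  constrained rigid-body refinement (`constrained_refine`,
  `refine_tilt_geometry`) and FSC with the 0.143 criterion (`compute_fsc`);
* MRC2014, `.tlt`/`.xf` and tab-separated particle-table I/O plus a CLI
  (`cli`) binding every stage.

See `vignettes/bisectr-methods.Rmd` for the models, assumptions, parameter
defaults and limitations.

## Worked example

Run a closed-loop acquisition session over the bundled 25-tilt ±36° scheme
with 200 nm stage jitter, 0.1 µm grid topography and the 100 nm / 5 nm
two-level thresholds, then compare eucentric-corrected vs planar targeting:

```r
library(bisectr)
scene  <- make_grid_scene(seed = 5)           # 5x5 holes, 2.5 um pitch
scheme <- scheme_fixture("pm36")

on  <- run_bisect_session(scene, scheme, session_config(TRUE),  seed = 5)
off <- run_bisect_session(scene, scheme, session_config(FALSE), seed = 5)
max(attr(on, "tracking")$true_residual_nm)
#> [1] 3.528084
summarize_session(on)$overall[, c("median_err_y_um", "median_defocus_err_um")]
#>   median_err_y_um median_defocus_err_um
#> 1     0.002123993            0.01098917
summarize_session(off)$overall[, c("median_err_y_um", "median_defocus_err_um")]
#>   median_err_y_um median_defocus_err_um
#> 1      0.01774479            0.07055894
```

Tracking stays within a few nanometres of ground truth over the whole
series (the design bound is 10 nm), and switching the per-ROI
eucentric-height fit on cuts the median in-plane targeting error from
~18 nm to ~2 nm and the median defocus error from ~71 nm to ~11 nm on the
same seed — the off-plane correction is what makes multi-target collection
usable on a non-planar support.

Downstream, a 100-particle simulated dataset with dose-dependent radiation
damage scores, weights and reconstructs like this:

```r
sim <- simulate_particle_dataset(n_particles = 100,
                                 scheme = scheme_fixture("pm36"), seed = 11)
sc  <- score_projections(sim$stack, sim$phantom, sim$meta, pixel_size = 3)
w   <- derive_exposure_weights(sc, sim$meta$tilt_index, c_A2 = "log")
rec <- weighted_reconstruct(sim$stack, sim$meta, pixel_size = 3, weights = w)
compute_fsc(rec$half1, rec$half2, 3)$resolution_A
```

Per-tilt mean scores decay with accumulated dose, the derived B factors
grow with acquisition order, and the weighted half-map FSC crosses 0.143
at a finer resolution than the unweighted reconstruction of the same data.

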