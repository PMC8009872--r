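---
title: "Models and methods behind bisectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bisectr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bisectr)
```

# Scope

`bisectr` is a desk-scale implementation of the computational core of
beam-image-shift multi-target cryo-electron tomography acquisition and of
constrained single-particle-style processing of the resulting tilt-series:
tilt schemes, targeting geometry, iterative tracking, a closed-loop virtual
stage, per-tilt astigmatic CTF estimation on tilted micrographs, and
score-driven exposure-weighted reconstruction. Nothing here talks to a
microscope; the acquisition side runs against a seeded simulator whose
purpose is to make the geometry and the control loop testable.

# Acquisition geometry

The specimen frame has `x` along the tilt axis, `y` perpendicular to it in
the untilted plane, and `z` along the beam toward the source; positive tilt
rotates `+y` toward `+z`:

$$y' = y\cos\theta + z\sin\theta, \qquad z' = -y\sin\theta + z\cos\theta.$$

`y'` is the apparent in-plane position a beam-image-shift (BIS) correction
must target, `z'` the height along the beam the focus setting must absorb.
Angles are degrees at every interface; stage geometry is in micrometres,
spatial frequency in 1/Å, defocus in Å with underfocus positive.

A target that is co-planar with the tracking area (`z = 0`) needs only the
planar correction `y' = y\cos\theta`; real supports are not planar, and a
height offset as small as 0.1 µm displaces the target by
`z\sin\theta` ≈ 60 nm at 36°, several times the high-magnification field
tolerance. `fit_eucentric()` recovers `(y_0, z_0)` per target from the
tracked apparent positions by closed-form linear least squares on the
rotation model (the design matrix has columns `cos θ`, `sin θ`). The fit is
ordinary and unweighted, is refit from all accumulated points after every
tilt, and starts once five points are available (before that the controller
uses the planar model). Observations whose simulated correlation peak falls
below a floor are excluded; an optional second pass drops residual outliers
beyond `3·RMS`.

# Tilt schemes

`generate_grouped_dose_symmetric()` produces dose-symmetric acquisition
orders: starting at 0°, branch visits alternate sign, and the k-th visit
extends its branch until it *leads* the other by `group_schedule[k]`
increments. Schedule 1 gives the classic order `0, 3, −3, −6, 6, 9, −9, …`;
larger groups trade symmetry for fewer stage reversals. Real sessions often
use irregular, throughput-motivated group structures; two such sequences
(±60° in 41 tilts, ±36° in 25 tilts, both 3° steps) ship as data files and
are validated as data (`validate_scheme()`), not claimed as generator
output. Dose bookkeeping is linear: `accumulated_dose()` with 3 or
5 e⁻/Å² per tilt reaches ~120–125 e⁻/Å² over a series.

# Tracking and the virtual stage

Tracking measures the displacement of the current view against the **first**
image of the series at the same magnification (first-image referencing
avoids the error accumulation of chaining along a branch). The tilted image
is first cosine-stretched by `1/cos θ` perpendicular to the tilt axis so it
can be correlated with the untilted reference; images are mean-subtracted,
Hann-apodized and band-pass filtered before circular cross-correlation, and
the peak is localized to sub-pixel precision by parabolic interpolation
(ties break toward the smallest shift). The loop is verify-after-correct: a
new image is acquired after each applied correction and the measurement
repeats until the residual falls below the level threshold (100 nm coarse,
5 nm at the target magnification) or `max_iterations` (5) is reached;
non-convergence is reported, not raised.

The virtual stage draws fresh Gaussian in-plane jitter (default σ = 200 nm
per axis, accumulating across moves) at every mechanical tilt, has a fixed
eucentric height offset (default 0.25 µm) for the session, and applies
image shift exactly. The rendered tracking views contain a smooth random
background texture (~400 Å correlation length) and dark gold-bead
fiducials, foreshortened by `cos θ` perpendicular to the axis, with
Poisson counting noise at a low tracking dose (0.5 e⁻/Å² per shot).

Two simulator choices matter and are deliberate:

* **Fields of view, not pixel sizes, are preserved.** The simulated
  detector is 128 px; the low- and high-magnification pixel sizes (160 and
  30 Å/px) are chosen so the fields of view (~2 µm and ~0.38 µm) match what
  the 100 nm / 5 nm thresholds assume on a 4k detector. Keeping the real
  per-pixel magnifications on a 128-px detector would make accumulated
  200 nm jitter exceed the correlation half-field — a wrap-around artefact
  of the small detector, not a property of the method.
* **The session starts centred.** The initial mechanical positioning error
  is compensated before the reference images are taken, as an operator does
  when selecting targets.

Ground truth is logged per tilt as the displacement of the specimen point
that sat at the centre of the reference image (the reference's own baked-in
offset foreshortens with `cos θ`, which the bookkeeping accounts for). With
the default configuration the maximum true residual over a 25-tilt series
is 2–4 nm, comfortably below the 10 nm precision bound the two-level
thresholds are designed to deliver.

Per-ROI targeting observations feeding the eucentric fits are analytic
(true apparent position + 5 nm measurement noise + occasional high-tilt
outliers carrying a low simulated peak) rather than rendered ROI exposures;
rendering 25 extra image stacks per tilt would multiply runtime without
exercising different code paths.

# Per-tilt astigmatic CTF estimation

The CTF model is `CTF(f, φ) = −sin(χ + arcsin w)` with
`χ = πλΔz(φ)f² − (π/2)C_sλ³f⁴ + Δφ` and
`Δz(φ) = ½[(z₁+z₂) + (z₁−z₂)cos 2(φ−φ_a)]`, underfocus positive,
`z₁ ≥ z₂`, `φ_a ∈ [−90°, 90°)` (violations are canonicalized by swapping
the pair and rotating the angle by 90°).

A tilted micrograph has a defocus gradient: at image position `r`, the
local defocus is the nominal value plus
`d_⊥(r)·tan(tilt)` where `d_⊥` is the distance from the tilt axis through
the field centre. `synth_tilted_micrograph()` synthesizes this by filtering
a white-noise specimen with a bank of CTFs at ≤100 Å defocus steps,
blending linearly between planes, and adding Poisson noise at the stated
dose (default 3 e⁻/Å², specimen contrast 12 %).

`tilted_power_spectrum()` implements the corrected power spectrum: tiles
(128 px, 50 % overlap) are Fourier-transformed, and each tile's spectrum is
radially rescaled by `sqrt(Δz_c/Δz_local)` — Thon-ring radii scale as
`1/sqrt(Δz)` — before averaging, using the *known* tilt geometry rather
than searching for it. The centre-defocus hint comes from a coarse
astigmatism-free fit on tiles within 150 Å of the axis
(`estimate_center_defocus()`). Fitting is two-stage: a mean-defocus grid
search on the background-subtracted radial average (background = order-4
polynomial in `|f|` over the fit band), then Nelder–Mead refinement of
`(z₁, z₂, φ_a)` maximizing the normalized correlation between the model
`|CTF|` and the background-subtracted 2D spectrum over the fit annulus
(40–10 Å by default at 4 Å/px), with restarts at ±45° to avoid the
astigmatism-angle local optimum. The fit score is that correlation; the
fit resolution walks a sliding-window correlation of 1D radial profiles
outward from the first shell that locks on (≥ 0.5) — shells below the
first CTF zero carry no ring information and are skipped.

**Field-size limitation.** On a 512-px, 4 Å/px field (0.2 µm) the 51°
gradient spread across tile centres is ~3800 Å: rings inside the 40–10 Å
band are attenuated but not destroyed when the correction is disabled, so
uncorrected mean-defocus recovery often still lands within 500 Å. Full
ring washout inside the band — the regime where uncorrected estimation
visibly fails on real 4k data — needs a ≥1 µm field, out of desk-scale
budget. The corrected/uncorrected comparison therefore reads the paired
fit score and ring contrast, which degrade consistently, rather than the
recovery tolerance.

# Constrained reconstruction and exposure weighting

Particle projections are processed directly from the tilt-series. The
combined orientation of one projection is `R_tilt(θ, axis) · R_particle`
with `R_particle` an intrinsic ZYZ rotation; the tilt transform composes on
the left. All slice extraction and insertion run on 2× Fourier-oversampled
grids (zero-padded real space) with trilinear interpolation, and
reconstruction divides out the resulting separable sinc² envelope after
cropping; this keeps the gridding error of a noiseless round trip below
~1 % over the particle support.

* `assign_particle_defocus()` adds the particle's height along the beam
  (`z' = −y sinθ + z cosθ`, converted to Å) to both defocus components of
  that tilt's CTF.
* `extract_particle_projections()` projects 3D positions through each
  tilt transform (plus the `.xf` in-plane transform), cuts integer boxes
  and records the sub-pixel remainder, marking tilts within half a box of
  the edge as not visible.
* `score_projections()` compares each projection to the CTF-modulated
  reprojection of the reference at its combined orientation and shift;
  the score is the **absolute** normalized cross-correlation over a
  scoring band (20–8 Å default) deliberately separate from the
  frequencies judged by FSC.
* `constrained_refine()` refines one rigid body per particle (3 Euler
  angles + a 2D shift in the untilted specimen plane, projected through
  each tilt), maximizing the mean band-limited |CC| across all its tilts;
  excursions beyond the search budget, or refinements that do not improve
  the score, are reverted and flagged. A second stage
  (`refine_tilt_geometry()`) re-estimates the tilt-axis angle (and
  optionally per-tilt angle offsets) against all particles of a series;
  in-plane shifts stay with tracking/alignment.
* `weighted_reconstruct()` inserts `w·CTF·data` and accumulates
  `w·CTF²` by direct Fourier insertion, with a per-shell Wiener constant
  (10 % of the shell-mean denominator) and half-maps split by particle-id
  parity so the halves share no particle.

## Exposure weights

Mean scores per tilt are converted to per-tilt isotropic B factors
relative to the best tilt, and weights `w_i(f) = exp(−B_i f²/4)`; the best
tilt is never attenuated and no weight exceeds 1. Two conversions are
available:

* linear, `B_i = c·(s_max − s_i)` with `c = 100 Å²` per unit score — the
  interface default;
* self-calibrated (`c_A2 = "log"`), `B_i = (4/f0²)·ln(s_max/s_i)` with
  `f0` the scoring-band centre. At low SNR the band-limited score is
  proportional to signal amplitude, so the log ratio reads the relative
  attenuation directly and needs no free constant.

The linear default with realistic score losses (~0.1) yields B ≈ 10 Å² —
less than 4 % attenuation anywhere in band, i.e. effectively no filter;
the log conversion recovers B of the order of the true radiation damage
and is what the package's own acceptance tests use. `spectral_contribution()`
exposes the resulting per-tilt share of reconstruction weight per
frequency: high frequencies are carried by the early, low-tilt exposures.

## The synthetic particle world

`simulate_particle_dataset()` renders tilt-series micrographs containing
projections of an analytic ~70 Å phantom (Gaussian blobs in an approximate
3-fold dihedral arrangement, σ = 4.5 Å so spectral content persists to
half-Nyquist at 3 Å/voxel) at random positions (thin slab, |z| ≤ 0.04 µm)
and uniform orientations, each modulated by a per-tilt astigmatic CTF at
the particle's depth and attenuated by a cumulative-dose B factor
`B_dose = 12 Å² per e⁻/Å² × accumulated dose`. The slope follows the
canonical critical-exposure curve: amplitude halves by ~15 e⁻/Å² at the
10 Å scale, giving `dB/d(dose) = 2/(N_e f²) ≈ 12–17 Å²` per e⁻/Å² there.
Gaussian readout noise of fixed σ makes the per-projection SNR decay with
accumulated dose; with the default noise the band-limited scores fall in
the 0.1–0.3 range typical of low-dose tomographic projections. Projections
are then re-extracted through the real extraction code path.

What the generator does *not* emulate: beam-induced per-tilt motion,
alignment errors in the `.xf` transforms, ice-gradient backgrounds,
neighbouring-particle overlap, and beam tilt/coma. A green test therefore
establishes the correctness and internal consistency of the geometry,
weighting and reconstruction machinery under the stated noise and damage
model — not performance on real micrographs.

## Statistical notes on the acceptance checks

* Adjacent tilts differ by a single 5 e⁻/Å² exposure; differences between
  neighbouring mean scores are below the sampling noise of 100-particle
  means, so B-factor growth with acquisition order is asserted as a strong
  monotone trend (Spearman > 0.9 and last-block vs first-block), not
  pairwise strictness.
* The per-shell FSC comparison between weighted and unweighted
  reconstructions is restricted to shells that still carry signal (either
  curve above 0.143). Beyond the crossing, both per-shell values are
  zero-mean noise statistics and demanding an ordering there would fail
  for any pair of finite-sample curves.

# Numerical choices

* FFTs via `stats::fft`; centred transforms put both the real-space origin
  and DC at `floor(n/2)+1`.
* Bilinear/trilinear interpolation with edge fill (image mean for
  stretched views, 0 for Fourier samples outside the grid).
* Sub-pixel correlation peaks by separable parabolic interpolation,
  clamped to ±0.5 px; equal peaks break toward the smallest shift.
* Defocus fitting: grid search step 500 Å, Nelder–Mead refinement with
  ±45° astigmatism-angle restarts; fit band 40–10 Å at 4 Å/px.
* Wiener constant: 10 % of the per-shell mean denominator (configurable);
  empty half-sets return zero maps rather than NaN.
* FSC resolution at a threshold is read at the first downward crossing by
  linear interpolation; a curve that never crosses reports the finest
  shell.
* All stochastic operations consume the R session RNG seeded once per
  entry point (`seed` arguments); derived streams use a fixed integer
  hash, keeping every derived seed below 2³¹.

# Known limitations

* The acquisition simulator has no stage backlash, no per-hole
  ice-thickness model and no optics aberrations (all out of scope).
* Tracking robustness at very large content shifts is bounded by the
  128-px simulated detector; the session design (initial centering,
  coarse-level field of view) keeps operation far from the wrap limit.
* Uncorrected-spectrum degradation at 51° is bounded by the 0.2 µm field
  (see above).
* The geometry refinement stage refines the axis angle and per-tilt angle
  offsets only; per-tilt in-plane shifts are assumed handled by
  tracking/alignment upstream.
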