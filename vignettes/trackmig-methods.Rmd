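---
title: "Migration statistics from nucleus tracks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration statistics from nucleus tracks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmig)
library(dplyr)
```

trackmig measures how cells move from time-lapse fluorescence microscopy of
labeled nuclei: how fast (speed), where to (angle of trajectory), how
persistently (angle of deflection and persistence time), and how collectively
(the paired random migration index, PRMI). This vignette explains the models
behind each statistic, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical decisions a careful user should know about.

## Coordinates, units and the interval size

Images use the screen convention: the origin is the center of the top-left
pixel, x grows rightward, y grows **downward**, frames are 0-based. All
positions are stored in pixels; physical conversion happens in one place,
through `acquisition(pixel_size_um, frame_interval_min, interval_size)`.
Defaults (1.314 µm/px, 7 min/frame) describe a 10× wide-field system with 2×2
pixel binning, a common regime for overnight migration assays.

Angles, however, are reported compass-style in a y-up frame, so that "up on
screen" is 90°: a cell moving up-and-right at equal rates has a trajectory
angle of 45°. The flip between conventions happens exactly once, inside
`angle_of_trajectory()`; nothing else ever negates y.

The third acquisition parameter is the **interval size** `a` (frames).
Sub-cellular motion and localization error make nucleus positions vibrate at
the single-frame scale, which badly inflates angular statistics. All angular
quantities are therefore computed between frames `n` and `n + a`, *sliding n
one frame at a time* (overlapping intervals — a track of `L` frames yields
`L − a` values, not `L/a`). The default `a = 3` (21 minutes at the default
frame rate) suppresses the jitter while keeping genuine turns; the gain from
going beyond `a ≈ 3` is small, which the test suite checks as a property
(mean and spread of |deflection| non-increasing in `a`, with diminishing
returns from 3 to 5).

## Per-cell kinematics

For each track row at frame `n`, at interval size `a`:

* **displacement** `d = |p(n+a) − p(n)|` in px, and speed
  `d · pixel_size · 60 / (frame_interval · a)` in µm/h;
* **angle of trajectory** Θ ∈ [0, 360): the compass direction of that
  displacement. A zero displacement has no direction and is *undefined*
  (`NA`), never 0° — otherwise stationary cells would fake eastward motion.
  Undefined values are excluded from every aggregate and from the direction
  histogram;
* **angle of deflection** ∈ (−180, 180]: the signed smallest rotation from
  the `(n, n+a)` leg to the `(n+a, n+2a)` leg — consecutive, non-overlapping
  legs sharing the endpoint `n + a`, again sliding `n` by one. Clockwise
  (decreasing compass angle) is positive. An exact 180° reversal maps to
  +180 to keep the range half-open; with sub-pixel centroids this is a
  measure-zero event;
* **MSD** at lag `n − first frame`, averaged over *all* overlapping start
  pairs of the track (the standard estimator; computing it from the track
  start only is the main alternative, and gives noisier curves).

Population summaries per frame report the mean displacement, the arithmetic
mean trajectory angle (the classic output field — kept for continuity even
though it is discontinuous at the 0/360 wrap; the circular mean is exposed
alongside as `circ_mean_theta_deg`), the percentage of cells turning by more
than 90°, the mean |deflection| (the population persistence readout: lower =
more persistent), and a 360-bin direction histogram.

## Persistence time

The persistent-random-walk model links MSD to speed `S` and persistence time
`P`:

$$\mathrm{MSD}(t) = n_d\, S^2 P \left(t - P\,(1 - e^{-t/P})\right), \qquad n_d = 2 .$$

Short lags are ballistic (`≈ n_d S² t² / 2`), long lags diffusive
(`≈ n_d S² P t`). `fit_persistence()` estimates `(S, P)` by unweighted
nonlinear least squares (Levenberg–Marquardt) on the population-averaged MSD
— robust at 7-minute sampling — with per-cell fitting available via
`fit_persistence_per_cell()`.

Numerical choices:

* **Multi-start.** The model is nearly flat in `P` once `P` exceeds the
  sampled lags, so a single start can stall on the plateau. Starts are
  `P ∈ {frame interval, 30, 120, 480}` min with `S` seeded from the
  ballistic limit of the first MSD point; the best converged start by
  residual sum of squares wins. Relative tolerance 1e-10.
* **Fit window.** Lags of 0–240 min by default: persistence fits
  conventionally sample a few hours of lags; much longer lags add little
  information about `P` and much boundary/confinement artifact.
* **Honest flags.** A fit whose `P` lands at or beyond the top of the lag
  window is unidentifiable — a straight mover looks persistent at every
  measurable scale — and is flagged `converged = FALSE` with the estimate
  still reported. If no start converges, `P` is `NA`.

A subtlety worth knowing: data sampled at discrete 7-minute frames exceed
the continuous-time model at lag 1 by ≈ 8% (the discrete walk has not yet
"turned inside" a frame). The effect decays by lag 2 and biases fitted `P`
slightly low (≈ 10–14% at `P = 30` min). The test suite pins the simulator
against the exact discrete-time closed form and tolerates this known bias in
the recovery checks.

## Collective migration: the PRMI

For pairs of neighboring cells, the pairwise *sample* standard deviation of
their two trajectory angles is `|Θₐ − Θᵦ| / √2`. The PRMI is the mean of
this quantity over pairs, pooled over the frames of the analysis window:
0 for perfectly collective motion, and `E|Θₐ − Θᵦ|/√2 = 120/√2 ≈ 84.85°`
for independent uniform directions — the null ceiling (~85°).

* **Pairs.** "Nearest neighbor within 100 µm" is read as: each cell's single
  nearest other cell, kept when the centroid distance is ≤ 100 µm, with
  reciprocal duplicates collapsed. The alternative reading — all pairs
  within the radius — is available (`pairing = "all_within"`), and the
  choice is recorded in the output.
* **Wrap exclusion.** The SD is computed on raw angle values, so a pair like
  (10°, 350°) would score 240° despite near-identical directions. Pairs with
  one angle in [0°, 90°] and the other in [270°, 360°) are therefore
  excluded. With the sample-SD convention the uniform-angle ceiling is
  84.85°; the population-SD convention would put it at 60°, and applying the
  exclusion to the random-angle control would put it at ≈ 69.7° — both
  incompatible with the ~85° null, which fixes both conventions.
* **Controls.** `random_pairing` re-draws each cell's partner uniformly
  among that frame's cells (distance ignored; exclusion still applied):
  if the PRMI rises, alignment is local, not global. `random_angles`
  replaces every angle by an iid uniform draw (exclusion *not* applied, per
  the ceiling argument above): the pure null, independent of positions and
  of the data. Both consume an explicit seed and are bit-reproducible.
  Values from fewer than ~100 pairs trigger a warning.
* **Sheets.** `leading_edge_profile()` bins cells by distance from the free
  edge (the extreme occupied coordinate along a user-chosen axis at each
  window's start) and reports a per-bin PRMI, with under-populated bins
  reported as `NA` rather than 0.

## Detection and linking

The detector follows the standard single-particle chain for fluorescent
point-like objects: background subtraction and low-pass at the nucleus scale
`w` (Gaussian of σ = w/3 minus a (2w+1)² boxcar, clamped at zero); candidate
pixels in the top `percentile` fraction of each frame's intensities that are
local maxima in a (2w+1)² window (plateau ties keep the lexicographically
smallest (y, x)); iterative intensity-weighted centroid refinement on a disk
of radius `w` (re-centering while the shift exceeds 0.5 px), yielding
sub-pixel positions and intensity moments `m0`, `m2`; and a moment filter
dropping detections with effective radius `sqrt(m2/m0)` below a cutoff
(hot pixels score near zero, real nuclei near `σ√2`). Because the threshold
is a per-frame quantile, detection is invariant to affine intensity
rescaling, and photobleaching does not starve late frames.

Linking is greedy ascending-cost assignment between active track ends and
the next frame's detections, gated at `max_disp` px per frame stepped; at
the nuclear densities this pipeline targets (tens of µm spacing vs a few
µm/frame motion) greedy assignment agrees with a global optimum and is far
easier to verify. Detections are canonically sorted before linking, so the
result is independent of input order. Gap closing across `link_range` missed
frames is available (default 1 = off); gaps are kept as frame skips — no
positions are invented — and the kinematics handles non-contiguous frames by
using actual frame differences. Tracks shorter than `min_track_length` are
dropped. Colliding nuclei that swap identity are accepted errors, as in all
trackers of this class.

## The synthetic generator

`simulate_prw()` generates the motion model the statistics assume: constant
speed `S`, heading incremented each frame by wrapped-normal noise of width
σ, uniform initial positions and headings, reflective walls (a microscope
field of view; both the position and the normal heading component mirror).
Wrapped-normal noise was chosen over von Mises because its directional
correlation is closed-form, `⟨cos Δθ⟩ = e^{−σ²/2}`, giving an analytic
ground-truth persistence time `P = 2·dt/σ²` (σ in radians) — so
persistence-recovery tests need no simulation-based reference.
`turn_sigma_for_persistence()` inverts the relation. Defaults — 300 cells
in a 1 mm² arena, 0.5 µm/min, σ = 39.14°/step (P ≈ 30 min at 7-minute
frames) — describe a low-density epithelial assay.

`simulate_collective()` adds Vicsek-style alignment: each heading relaxes by
weight `alignment_weight` toward the circular-mean heading within
`coupling_radius_um` before the noise is added; with `edge_gradient > 0` the
noise σ grows linearly with distance from the x = 0 edge, emulating order
decaying away from a sheet's leading edge. `render_video()` draws each
nucleus as an isotropic Gaussian spot at its sub-pixel position on a noisy
background, 16-bit clipped, so the whole pipeline can be closed against
ground truth.

What the generator deliberately does **not** emulate: mitosis and apoptosis,
cell–cell exclusion volumes (nuclei can overlap, which no intensity-based
detector can resolve — closure tests therefore use realizations whose
spacing exceeds the detector window), photobleaching, non-Gaussian PSFs, and
speed heterogeneity between cells. Passing tests demonstrate correctness of
the *statistics* under the stated motion model, not robustness to every
pathology of real microscopy data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script are sized for a laptop-class
run: populations of 150–1200 simulated cells, 15–100 frames, rendered images
up to ~785 px square; the full suite takes about three minutes. All
stochastic steps take explicit seeds, and every simulator and random control
is a pure function of (parameters, seed): identical inputs give
bit-identical outputs, including the CSV report bundles.

```{r example}
cfg <- acquisition()
tracks <- simulate_prw(prw_params(n_cells = 200, n_frames = 60, config = cfg),
                       seed = 42)
kin <- compute_kinematics(tracks, cfg)
fit <- fit_persistence(msd_curve(tracks, cfg, max_lag_frames = 35))
glance(fit)
```

## Known limitations

* The arithmetic-mean trajectory angle (kept for output continuity) is
  misleading for populations spanning the wrap; use `circ_mean_theta_deg`.
* The PRMI's wrap-exclusion makes it only approximately rotation invariant
  (< 2° variation for aligned populations); the random-angles ceiling is
  exactly invariant.
* Persistence estimates inherit the discrete-sampling bias described above;
  comparisons *between conditions* at the same frame rate are unaffected.
* Greedy linking assumes spacing well above per-frame motion; dense or fast
  populations need a global assignment method outside this package's scope.
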