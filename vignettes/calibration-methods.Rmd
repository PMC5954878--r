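---
title: "Methods: point-based probe calibration and its virtual test bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-based probe calibration and its virtual test bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probecal)
```

## The calibration model

A tracked 2D ultrasound frame becomes 3D data only through the rigid
transform from the image plane to the tracked probe body,
$^{P}\mathbf{T}_I$. `probecal` estimates it from point targets whose true
positions in a phantom frame are known from independent digitization. Each
segmented target $i$ gives one vector equation

$$
\begin{bmatrix} \bar x_{Ph_i} \\ \bar y_{Ph_i} \\ \bar z_{Ph_i} \\ 1 \end{bmatrix}
\approx
\left(^{Ph}\mathbf{T}_W\right)_i
\left(^{W}\mathbf{T}_P\right)_i
\,^{P}\mathbf{T}_I
\begin{bmatrix} s_x x_{I_i} \\ s_y y_{I_i} \\ 0 \\ 1 \end{bmatrix},
$$

and the six parameters of $^{P}\mathbf{T}_I$ — Euler angles
$(\alpha, \beta, \gamma)$ in z–y–x (axial–lateral–elevation) sequence and
translations $(x, y, z)$ along the probe's elevation/lateral/axial axes —
minimize the mean residual distance

$$
D = \frac{1}{n} \sum_{i=1}^{n}
\left\lVert \mathrm{truth}_i - \mathrm{mapped}_i \right\rVert .
$$

Because the truths are known in the phantom frame, the system is fully
determined even when every frame is acquired at a *single* viewing angle
(e.g. by stepping a clamped probe with a linear actuator): with a common
probe orientation the image points still span a 2D plane, which pins the
first two columns of the rotation, and orthonormality supplies the third.

Two readings of the residual formula are possible (sum of distances divided
by $n$, or distance of summed vectors divided by $n$); only the mean of
distances is dimensionally and statistically sensible for pooled reporting,
and that is what `residual_error()` computes.

### Assumptions

* All transforms are rigid; pixel scales $s_x, s_y$ are known exactly
  (scanner-reported) and strictly positive.
* Targets are segmented in the image mid-plane, i.e. the out-of-plane image
  coordinate is exactly zero. Elevation beamwidth effects appear only
  through the noise model, not as a geometric offset.
* Target truths, poses, and pixels refer to the same instant (stationary
  probe and phantom during each capture, so no temporal synchronization).

## Numerical choices

* **Objective.** The optimizer minimizes the *stacked 3n-vector* of
  phantom-frame residuals by Levenberg–Marquardt (`minpack.lm::nls.lm`)
  rather than the scalar $D$: the sum of squares is smooth where a sum of
  norms is not, and has the same minimizer in the noiseless limit. The
  reported `residual_mm` is always the mean-distance $D$.
* **Initialization.** Always from `closed_form_init()`: each truth is pulled
  back to the probe frame through the inverted tracked chain, and the scaled
  image points (a planar set) are registered onto those points by SVD
  absolute orientation with determinant-sign correction. The fit is
  therefore deterministic; no random restarts. On noiseless data the
  initializer already *is* the optimum, and the test suite uses that as an
  independent oracle for the nonlinear path.
* **Convergence.** Parameter-step tolerance `ptol = 1e-10`, at most 200
  iterations; both exposed as arguments. Non-convergence is reported via
  `converged = FALSE`, not an error. If (pathologically) the refined mean
  distance exceeded the initializer's, the initializer is returned.
* **Angles.** Radians internally, degrees in every file format and printed
  report. Angles normalize to $(-\pi, \pi]$. At gimbal lock
  ($|\beta| = \pi/2$) the $\alpha/\gamma$ split is fixed by the convention
  $\gamma = 0$, which still reconstructs the rotation exactly.
* **Degenerate inputs.** Fewer than 3 observations, or image points that are
  collinear (second singular value below $10^{-9}$ of the first), raise a
  degenerate-configuration error: a planar registration needs a 2D-spanning
  source set. Fewer than 3 or collinear markers likewise fail
  `pose_from_markers()`.

## Speed-of-sound correction

Scanners form images assuming $c_{cal} = 1540$ m/s. In room-temperature
water the true speed $c_a$ is lower, so echoes appear too deep along their
scan line. For a curvilinear probe each scan line is a ray from the
footprint's arc center; the segment beyond the footprint scales by
$c_a / c_{cal}$, giving

$$
\delta = (D_{im} - R)\left(1 - \frac{c_a}{c_{cal}}\right),\quad
\delta x = \delta \sin\theta,\quad \delta y = \delta \cos\theta,
$$

with corrected coordinates $(x + \delta x,\; y - \delta y)$; $\theta$ is the
angle between the ray and the axial direction, positive in the left half of
the image. The published typesetting of this relation is ambiguous about the
grouping; the adopted form is the only one that is exactly the identity at
$c_a = c_{cal}$ and linear in the in-tissue path length, which the test
suite asserts to $10^{-12}$. The correction operates on mm coordinates (the
only units in which $R$ is meaningful) and is written back to pixels so
corrected tables flow through the rest of the pipeline unchanged.

$c_a$ comes from `water_sound_speed()`, the fifth-order pure-water
polynomial of Marczak (1997, *J. Acoust. Soc. Am.* 102:2776–2779), valid
0–95 °C at atmospheric pressure; the source is cited in the function
documentation because the original hardware study cites an equivalent fit
without printing coefficients.

## Evaluation metrics

All four metrics return mean/SD/max/min plus the pooled count, with SD using
the $n-1$ denominator (the convention of mean (SD) tables):

* **Calibration reproducibility** — the 4 corners and the center of the
  rectangular image extent mapped to probe space with each calibration;
  distances pooled over all unordered calibration pairs × 5 points
  ($\binom{k}{2}\cdot 5$; 225 for $k = 10$). The rectangular bitmap extent is
  used as-is; the curvilinear fan is not cropped, matching the standard
  5-point protocol.
* **Point reconstruction precision** — a fixed pin head imaged from many
  views; pairwise distances of reconstructions pooled within and then across
  calibrations ($\binom{v}{2}\cdot k$; 1225 per calibration and 12,250 for
  50 views × 10 calibrations).
* **Point reconstruction accuracy** — distance of every view × calibration
  reconstruction to the digitized truth ($v \cdot k$; 500 for 50 × 10).
* **Distance reconstruction accuracy** — *signed* differences
  true − imaged over every (view A, view B, calibration) triple
  ($v_a v_b k$; 2500 image pairs per calibration, 25,000 for 10); signed
  because over- and under-estimation are both meaningful, and unlike the
  other three metrics its minimum can be negative.

## What the simulator emulates — and what it does not

`system_truth()` describes the virtual hardware: a 512 × 480 px image at
0.2 mm/px (102.4 × 96 mm), 90 mm depth setting, a curvilinear footprint of
radius 40 mm with a 30° fan half-angle, and a ground-truth calibration with
all six parameters away from trivial values (α ≈ 92.9°, β ≈ −2.3°,
γ ≈ 93.4°, t = (1.5, −48, 12) mm) so axis-ordering or sign bugs cannot hide
behind symmetry.

`acquisition_plan()` reproduces the stepped single-angle protocol: 6 depth
levels 10 mm apart with the most superficial at 35 mm, where the fan is
narrowest. The cross-wire target is re-imaged at 7 lateral positions per
level (5 at the most superficial level, whose lateral dimension is smaller),
and the 7-screw collinear phantom (15 mm spacing) is imaged once per level
with the field of view masking the outer screws at the top level — both
yield exactly 40 visible targets. *Central-only* coverage confines the
cross-wire placements to the middle fifth of the lateral extent. A middle
*third* was considered and rejected: full-FOV placements are necessarily
clipped to the bitmap, so the lateral-spread ratio between full and
middle-third coverage cannot exceed ≈ 2.9, too weak to reproduce the
pronounced axial-rotation degeneracy this coverage is meant to exhibit; a
middle-fifth band (spread ratio ≈ 4.7) does reproduce it.

Noise enters in two physically distinct places (`noise_model()`):

* **Segmentation noise** — isotropic Gaussian in pixels (default 2.5 px =
  0.5 mm), added to the exact projected pixel coordinates.
* **Tracker noise** — isotropic Gaussian on each IR-diode's *world position*
  (default 0.15 mm), after which the pose is refit by rigid registration of
  the 5-marker layout (`pose_from_markers()`). Modeling the tracker at the
  marker level rather than perturbing pose parameters directly reproduces
  the averaging benefit of redundant markers (5 markers track better than
  3 — a property the tests verify by Monte-Carlo) and yields pose errors
  with realistic rotation/translation coupling.

Both defaults are plausible magnitudes for careful manual segmentation and a
research-grade optical tracker, chosen once as the simulator's study
conditions; neither is a measured property of any specific hardware.

The tracker noise matters beyond realism. With purely in-plane segmentation
noise the simulator's out-of-plane geometry is *exact* (every target truly
lies in the image mid-plane), which pins the axial rotation α almost
noiselessly under any coverage — an artifact no physical system shows, where
elevation beamwidth and tracking error always blur the out-of-plane
constraint. With marker-level pose noise enabled, the expected degeneracy
appears: under central-only coverage the SD of recovered α across seeded
replicates inflates several-fold relative to full-FOV coverage, and
calibration reproducibility degrades accordingly.

The simulator does **not** model: B-mode image formation (speckle, PSF,
beamwidth), refraction or depth-dependent sound speed, probe-alignment error
dynamics, water temperature drift, or segmentation bias (its noise is
zero-mean). Passing tests therefore demonstrate the correctness of the
estimator and metrics under the stated error model, not the hardware error
magnitudes of any physical system — those depend on scanner, tracker, and
operator, and published values should be compared only qualitatively.

## Problem sizes used in the test suite

The suite's simulation studies use the protocol's natural sizes: 40-target
acquisitions, 10 seeded replicates per coverage condition for the degeneracy
check, 20 replicates per noise level for the noise-monotonicity property,
50 views × 10 calibrations for metric pooling, and 500 Monte-Carlo
replicates for the 5- vs 3-marker comparison. The full suite runs in well
under a minute on one core.

## Known limitations

* Calibration quality is reported through the four metrics; no closed-form
  covariance of the six parameters is provided (the Levenberg–Marquardt
  Jacobian could supply one, but pooled empirical metrics are the field's
  reporting convention).
* The solver assumes isotropic residual weighting; if pose noise dominates
  segmentation noise strongly, a weighted objective would be more efficient.
* The speed correction assumes a homogeneous medium between footprint and
  target (appropriate for a water bath, not layered tissue).
* `calibration_reproducibility()` evaluates the rectangular extent's
  corners even where a curvilinear image has no signal; this matches the
  standard protocol but slightly stresses extrapolated regions.
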