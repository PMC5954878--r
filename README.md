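# probecal

Point-based spatial calibration of freehand 3D ultrasound probes, with a
virtual phantom/tracker test bench.

## The problem

Freehand 3D ultrasound acquires spatially localized 2D images by tracking
the pose of a conventional probe with an external (typically optical)
tracker. The tracker reports the probe body's pose in the world frame, not
the image plane's — so 3D reconstruction needs the fixed rigid transform
**<sup>P</sup>T<sub>I</sub>** from the image coordinate system to the probe
coordinate system. Estimating that transform is *probe calibration*.

`probecal` implements the single-viewing-angle, point-target formulation:
each point target *i* segmented at pixel (x<sub>I</sub>, y<sub>I</sub>) maps
to the phantom frame through the tracked chain

```
[x_Ph, y_Ph, z_Ph, 1]' = (PhT_W)_i · (WT_P)_i · PT_I · [s_x·x_I, s_y·y_I, 0, 1]'
```

where s<sub>x</sub>, s<sub>y</sub> are pixel-to-mm scale factors and
(<sup>Ph</sup>T<sub>W</sub>)<sub>i</sub>, (<sup>W</sup>T<sub>P</sub>)<sub>i</sub>
are the tracked phantom and probe poses. Because the targets' true
phantom-frame positions (x̄<sub>Ph</sub>, ȳ<sub>Ph</sub>, z̄<sub>Ph</sub>) are
digitized independently, the six parameters of <sup>P</sup>T<sub>I</sub>
(z-y-x Euler angles α, β, γ and translations x, y, z) are found by minimizing
the mean residual distance

```
D = (1/n) Σ_i ‖ truth_i − mapped_i(α, β, γ, x, y, z) ‖
```

over the n targets — no reorientation of the probe between targets is
required, which is what makes actuator-stepped acquisition possible.

The package provides:

- **geometry** — rigid 4×4 transform algebra, z-y-x Euler conventions, and
  SVD-based absolute orientation (`fit_rigid`), which doubles as the
  closed-form initializer and the noiseless-case oracle;
- **calibration** — `map_image_to_phantom`, `residual_error`,
  `closed_form_init`, and `calibrate` (Levenberg–Marquardt on the stacked
  residual vector);
- **soundspeed** — ray-model correction for curvilinear probes
  (`correct_point`) and water sound speed from temperature
  (`water_sound_speed`, fifth-order polynomial, 0–95 °C);
- **metrics** — calibration reproducibility, point reconstruction
  precision, point reconstruction accuracy, distance reconstruction
  accuracy, each pooled with the standard combinatorics;
- **simulate** — a virtual test bench: cross-wire and 7-collinear-screw
  phantoms, actuator-stepped acquisition at 6 depth levels, full-FOV vs
  central-only coverage, Gaussian segmentation noise, and tracker noise
  injected at the IR-diode level (`pose_from_markers`).

## Worked example

```r
library(probecal)

truth <- system_truth()                      # virtual hardware + true P_T_I
plan  <- acquisition_plan("cross_wire")      # 40 targets over 6 depth levels
obs   <- simulate_observations(truth, plan, noise_model(seed = 42))
fit   <- calibrate(obs)
print(fit)
#> Probe calibration from 40 point targets
#> Image-to-probe calibration parameters
#>   alpha (axial z):        92.8763 deg
#>   beta  (lateral y):      -2.1201 deg
#>   gamma (elevation x):    93.3704 deg
#>   x (elevation):           1.5748 mm
#>   y (lateral):           -48.2263 mm
#>   z (axial):              11.9942 mm
#>   mean residual D: 0.658074 mm
#>   converged: yes (1 iterations)
```

The ground truth here is (92.86°, −2.29°, 93.44°, 1.5, −48, 12); under
0.5 mm segmentation noise and 0.15 mm tracker-marker jitter the solver
recovers the angles within ~0.2° and the translations within ~0.25 mm, with
a mean residual D of 0.66 mm (the injected noise floor). Repeating the
calibration and evaluating it:

```r
calibs <- lapply(1:5, function(s) calibrate(simulate_observations(
  truth, plan, noise_model(seed = s)))$params)
calibration_reproducibility(calibs, truth$width_mm, truth$height_mm)
#> mean 0.2018 (SD 0.1128), max 0.4991, min 0.0473, n = 50

views <- simulate_views(truth, n_views = 50, noise = noise_model(seed = 99))
point_reconstruction_accuracy(views, calibs, attr(views, "pin_world"))
#> mean 0.7220 (SD 0.3827), max 1.8747, min 0.0507, n = 250
```

Reproducibility pools the probe-space distances of 5 fixed image points over
all calibration pairs (choose(5,2)·5 = 50 here); accuracy pools the error of
every view × calibration reconstruction of a fixed pin head against its true
world position.

A command-line front end with `simulate`, `calibrate`, `evaluate` and
`correct` subcommands is installed at
`system.file("cli", "probecal.R", package = "probecal")`.

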