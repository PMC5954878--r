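Package: probecal
Title: Point-Based Spatial Calibration of Freehand 3D Ultrasound Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for spatial calibration of tracked (freehand 3D)
    ultrasound probes from point-target phantoms imaged at a single
    viewing angle. Provides rigid-transform and Euler-angle utilities,
    closed-form initialization and nonlinear least-squares estimation of
    the six image-to-probe calibration parameters, ray-model speed-of-sound
    correction for curvilinear transducers, the four standard precision and
    accuracy metrics (calibration reproducibility, point reconstruction
    precision, point reconstruction accuracy, distance reconstruction
    accuracy), and a virtual phantom/tracker simulator for testing
    calibration workflows without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
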