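Package: boutkin
Title: Swim Bout Segmentation and Balance Kinematics for Vertical
    Locomotion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for videographic assays of posture and vertical
    locomotion in small animals, centred on larval zebrafish. Reads and
    writes the per-frame '.dlm' acquisition format, re-implements the
    real-time single-animal detection and orientation algorithm on grayscale
    frames, segments swim epochs into peak-speed-aligned bouts and buffered
    inter-bout intervals, derives per-bout kinematic features (trajectory,
    attack angle, steering and righting rotations), fits the four balance
    models (posture-dependent bout timing, steering gain, fin-body
    coordination, righting gain and set point), and provides a
    resampling-based framework for confidence-interval width and Cohen's d
    effect-size (power) estimation. A synthetic-data generator with known
    ground-truth parameters makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    EBImage,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
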