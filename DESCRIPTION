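Package: muscleval
Title: Validation of Single-Camera Musculoskeletal Muscle-Force Estimates
    Against Marker-Based Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale musculoskeletal pipeline for comparing muscle
    forces estimated from a sparse single-camera joint-centre stream with
    those estimated from a dense marker-based stream. Ships a simplified
    thoracoscapular shoulder-elbow model with a published muscle parameter
    registry, a synthetic-data generator for dumbbell exercises (lateral
    fly, biceps curl) that renders both measurement streams with
    pose-estimation-like degradation, and the full processing chain:
    joint-centre estimation, quality control, static-pose scaling,
    weighted least-squares inverse kinematics with prescribed
    scapula/clavicle coordinates, inverse dynamics with the dumbbell load
    at the hand, static optimization of squared muscle activation, and
    the validation statistics (RMSD in N and %Fmax, Pearson correlation
    categories, Bland-Altman agreement) with trial-to-subject-to-grand
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
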