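Package: omat
Title: Objective Movement Assessment from Optical and Simulated Inertial Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies athletes as elite or novice from movement-screen
    kinematics using a principal-component pattern-recognition pipeline.
    Supports an optical-marker variant (whole-body joint-centre and marker
    trajectories) and a simulated inertial-sensor variant (Euclidean norms of
    segment linear accelerations and angular velocities), ensemble feature
    selection by rank voting over six ranking techniques, seven classifiers
    evaluated with leave-one-out cross-validation re-fitting the whole stack
    in every fold, and signal-detection-theory metrics (d-prime, criterion).
    Includes a synthetic-cohort generator with controllable class separation
    in movement smoothness and amplitude, and readers/writers for TRC, C3D
    and wide-CSV motion-capture formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    MASS,
    class,
    e1071,
    rpart,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
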