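Package: chewkin
Title: Marker-Based Jaw Kinematics for Proal Chewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs six-degree-of-freedom jaw kinematics from 3D
    marker trajectories recorded with biplanar videoradiography (XROMM-style
    workflows). Provides least-squares rigid-body pose estimation from marker
    constellations, anatomical coordinate systems built from occlusal-plane
    landmarks, Grood-Suntay-style joint coordinate systems at the
    temporomandibular joint and mandibular symphysis, chew-cycle segmentation
    and time-normalization, per-cycle amplitude statistics with between-cycle
    confidence intervals, and workflow-precision estimation from zero-motion
    (cadaver) trials. Includes a synthetic proal-chewing trial generator with
    analytic ground truth so every pipeline stage is testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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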