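Package: exprfeat
Title: Facial Expression Features from Fused Uniform LBP and Region-Balanced ORB
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for facial
    expression recognition on low-compute hardware. Crops a standardized
    130x130 face region from 68-point facial landmarks, computes
    uniform-pattern local binary pattern (LBP) patch histograms and a
    region-balanced ORB descriptor (FAST corners with a per-region keypoint
    budget, intensity-centroid orientation, steered 256-bit BRIEF), fuses the
    two feature families by per-block Z-score standardization, and evaluates
    a support vector machine under subject-dependent and subject-independent
    repeated 10-fold cross-validation. Includes a deterministic synthetic
    face generator with known landmarks, class-dependent texture and planted
    corners so the whole pipeline is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    e1071,
    optparse,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
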