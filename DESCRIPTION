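Package: hifumotion
Title: Tissue Motion Modeling and Prediction for Ultrasound-Guided Focused Ultrasound Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation, simulation and parameter estimation for predicting the
    movement and deformation of soft tissue pressed by a rigid instrument during
    ultrasound-guided high intensity focused ultrasound (HIFU) therapy. Provides a
    geodesic localized Chan-Vese (GLCV) level-set segmenter for speckled, low-contrast
    ultrasound-like images; a multiphase smoothed particle hydrodynamics (SPH)
    simulator coupling fluid, elastic tissue (Green-Saint-Venant strain with moving
    least squares gradients) and rigid bodies; an iterative contour-matching
    parameter-estimation algorithm; contour agreement metrics (Dice, MSSD, Hausdorff);
    and seeded synthetic generators for phantom images and observation series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    grDevices,
    utils,
    tools,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
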