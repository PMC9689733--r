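Package: pearnir
Title: Near-Infrared Calibration Pipeline for Mineral Content of Pear Fruit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating near-infrared (900-1700 nm)
    calibration models that predict calcium, boron and potassium content in
    the pulp and peel of pear fruit. Covers reflectance calibration from raw
    detector counts, thirteen named spectral pretreatments (Savitzky-Golay
    smoothing, multiplicative scatter correction, standard normal variate,
    derivatives, log transform and their compositions), partial least squares
    regression (NIPALS) and gradient boosted regression trees, genetic-algorithm
    wavelength selection against a cross-validated fitness, and model grading by
    the ratio of performance to deviation (RPD). A synthetic cohort generator,
    calibrated to published cohort statistics, plants analyte absorption bands
    in a Beer-Lambert reflectance model with multiplicative scatter so every
    pipeline stage is testable without instrument data.
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
    purrr,
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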