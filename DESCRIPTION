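Package: echotrace
Title: Validation Toolkit for Combined Ultrasound Imaging and High-Density
    Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for validating combined
    B-mode ultrasound and high-density surface electromyography (EMG)
    acquisition systems. Generates synthetic speckle image sequences with
    exact displacement ground truth (oscillating spring phantoms and
    twitching pennate-muscle scenes), trigger-locked multichannel M-wave
    recordings with realistic failure modes, and electrode-interface test
    signals. Provides normalized cross-correlation region tracking with
    sub-pixel refinement, Kanade-Lucas-Tomasi sparse feature tracking with
    probe-grid interpolation, M-wave template averaging and normalized
    mean square error mapping over electrode grids, electrode-skin noise
    and impedance estimation, and the statistical battery (paired tests,
    factorial ANOVA, Kolmogorov-Smirnov comparison, Pearson correlation,
    model II regression) used to quantify agreement between imaging and
    detection conditions.
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
    interp,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    deldir,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
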