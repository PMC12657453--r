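Package: kneegait
Title: Downstream Gait Analysis for Markerless Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of markerless motion-capture walking trials:
    readers and writers for OpenSim-style TRC marker and MOT joint-angle text
    files, Savitzky-Golay signal conditioning, automatic heel-strike and
    toe-off detection from vertical marker displacement, gait-cycle
    segmentation with quality control, spatiotemporal and peak joint-angle
    parameter extraction, group comparison statistics (Welch t, chi-square,
    Cohen's d), and phase-wise bootstrap confidence bands with
    significant-region detection on time-normalized kinematic curves.
    Includes a synthetic two-group gait cohort generator with ground-truth
    events and parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
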