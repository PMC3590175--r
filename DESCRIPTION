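Package: restalff
Title: Amplitude of Low-Frequency Fluctuation and Seed-Based Connectivity
    Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxel-wise amplitude of low-frequency fluctuation (ALFF)
    analysis of resting-state BOLD fMRI with global-mean standardization,
    two-sample group comparison with Monte-Carlo (AlphaSim-style)
    cluster-extent correction, seed-based functional connectivity from
    spherical regions of interest with head-motion nuisance regression and
    Fisher z-transformation, and partial correlation of regional ALFF with
    clinical covariates.  Includes a synthetic two-group BOLD cohort
    simulator with planted amplitude and connectivity effects for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
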