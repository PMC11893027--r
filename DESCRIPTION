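Package: fetalt2star
Title: Regional Fetal Brain T2* Relaxometry with Slice-to-Volume
    Reconstruction and Gestational-Age Normative Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for regional T2* relaxometry
    of the fetal brain from dynamic multi-echo gradient-echo acquisitions.
    Provides a gestational-age-parameterised digital fetal-brain phantom with
    Rician noise and per-slice rigid motion, a simplified multichannel rigid
    slice-to-volume super-resolution reconstruction, voxelwise
    mono-exponential T2* mapping, seven-region quantification, cohort
    inclusion/exclusion bookkeeping, and normative gestational-age modelling
    (polynomial growth curves and two-week-bin percentile tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
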