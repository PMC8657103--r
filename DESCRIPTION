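Package: lesionkinetics
Title: Lesion-Level Volumetric Response, Hyperprogression and Dissociated
    Response Analysis for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lesion-level evaluation of response to immune checkpoint
    inhibitors from three-timepoint CT volumetry: tumor growth kinetics
    (TGK) ratios and volumetric hyperprogression (HPDv) calls per lesion,
    Nelson volumetric response categories, patient-level dissociated
    response (DR) classification, first-order intensity-histogram
    radiomics feature extraction from masked voxel patches, per-organ
    discrimination of HPDv with generalized estimating equations
    (exchangeable working correlation, robust sandwich covariance) and
    ROC/AUC, and Kaplan-Meier / log-rank comparison of overall survival
    between DR and non-DR patients.  Ships a synthetic cohort generator
    with controllable clustered outcome structure and a deterministic
    reference fixture, so the whole pipeline is exercisable without any
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
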