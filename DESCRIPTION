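Package: protonSelect
Title: Delineation-Based Decision Support for Proton Therapy Selection
    in Head and Neck Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts organ-at-risk mean doses for photon (VMAT) and
    proton (IMPT) head-and-neck plans directly from delineation
    geometry, using the percentage of each organ overlapping
    margin-expanded target volumes as linear-model predictors.
    Converts predicted doses to normal tissue complication
    probabilities (NTCP) for grade >=2 and grade >=3 xerostomia and
    dysphagia, forms the delta-NTCP profile between modalities, and
    applies national-protocol qualification thresholds to flag
    patients likely to benefit from proton therapy before any
    treatment plan exists. Includes margin-grid model fitting and
    selection, post-hoc sensitivity adjustments, diagnostic evaluation
    of predicted against actual plan-comparison decisions, voxel
    phantom and feature-level cohort simulators, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
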