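Package: symgeo
Title: Symptom-Improvement Geometry and Baseline Connectivity Mapping for
    Two-Arm Antidepressant Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven analysis of symptom improvement in
    placebo-controlled antidepressant trials. Computes item-level change
    matrices across multi-scale clinical panels and extracts their leading
    principal axes with permutation significance and split-half
    cross-validation reliability; builds a pooled common improvement axis
    and compares per-arm score distributions; derives parcel-level global
    brain connectivity (GBC) from parcellated resting-state time series
    with network, subcortical and whole-brain aggregation; and maps
    baseline GBC onto improvement scores via mass-univariate correlation
    with max-statistic permutation family-wise error control,
    treatment-interaction maps, and repeated-measures ANOVA with
    within-subject network strata. Includes a synthetic cohort generator
    with planted latent structure so the full pipeline is testable without
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
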