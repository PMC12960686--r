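Package: confunnel
Title: Conformal-Prediction Virtual-Screening Funnel with MD Stability Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of an AI-accelerated virtual-screening
    funnel for structure-based inhibitor discovery: docking-score labeling of
    computational actives, aggregated Mondrian (class-conditional) inductive
    conformal prediction with delta-p prioritization, a conjunctive ADMET
    filter cascade with funnel accounting, and molecular-dynamics trajectory
    stability analytics (RMSD, RMSF, radius of gyration with axis components,
    Shrake-Rupley SASA, hydrogen bonds, dynamic cross-correlation, free-energy
    landscapes, simplified secondary structure). A synthetic-library generator
    with a planted-signal docking oracle supplies ground-truth test beds in
    place of ultra-large compound databases and a docking engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    rlang,
    Matrix,
    xgboost,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pROC,
    withr
Config/testthat/edition: 3
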