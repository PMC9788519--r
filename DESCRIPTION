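Package: phenorevert
Title: Metabolic Phenoreversion Modeling for Longitudinal Serum Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discriminate acute-disease from healthy serum
    metabotypes with an orthogonal partial least squares discriminant
    analysis (O-PLS-DA) model built on a screened variable panel, project
    longitudinal samples onto it, estimate per-subject metabolic recovery
    times from linear score trajectories, and model the distribution of
    recovery times as a generalized extreme value (GEV) law. Includes a
    synthetic cohort generator with correlated lipoprotein blocks, planted
    acute effects, GEV-distributed recovery days and a coupled cytokine
    panel, so the full pipeline is testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
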