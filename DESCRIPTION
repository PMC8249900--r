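Package: connfinger
Title: Connectome Fingerprinting and Identifiability-Filtered Predictive Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for functional connectome fingerprinting and
    connectome-based predictive modeling (CPM) of cognitive outcomes.
    Test/retest functional connectomes are denoised by group-level principal
    component analysis: edge vectors from two sessions are stacked, the
    reconstruction sweep locates the number of components maximizing
    differential identifiability (the gap between within-subject and
    between-subject test/retest similarity), and connectomes reconstructed at
    that optimum feed a dual-session CPM variant (intersected edge masks,
    session-averaged coefficients and predictions). Includes edgewise
    ICC(2,1) reliability maps, a split-half cross-validation harness with
    stability, specificity and generalizability diagnostics, paired
    permutation tests with max-statistic family-wise correction, consensus
    edge masks with binomial resting-state-network enrichment tests and
    BrainNet Viewer export, and a seeded synthetic test/retest cohort
    generator with planted outcome-linked edge masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
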