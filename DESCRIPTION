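Package: hypernc
Title: Multi-Study Discovery of Non-Coding RNA Signatures of Skeletal
    Muscle Hypertrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering non-coding RNA genes linked to
    human skeletal-muscle hypertrophy across multiple resistance-training
    cohorts. Classifies subjects into lean-mass response groups against
    instrument technical-variation thresholds, performs Significance Analysis
    of Microarrays (SAM) paired and unpaired permutation differential
    expression with fudge-factor estimation, pools per-study expression/lean
    mass correlations with the Stouffer method and published heuristic
    filters, assembles the hypertrophy signature with inclusion-exclusion
    accounting, correlates candidates with cell-type marker panels, builds
    FDR-thresholded planar maximally filtered co-expression networks, and
    runs hypergeometric over-representation analysis against a custom
    background. Ships a seeded multi-study synthetic-data generator so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    yaml,
    withr
Config/testthat/edition: 3
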