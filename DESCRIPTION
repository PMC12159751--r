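Package: regdyn
Title: Regulatory Dynamics from Single-Cell Multiome Data Along Pseudotime
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting gene-regulatory dynamics from paired
    single-cell RNA and ATAC (multiome) data ordered along a differentiation
    pseudotime. Implements quality-control filtering, cluster marker
    detection, 50-cell pseudobulk aggregation, correlation-based
    peak-to-gene linking with k-means clustering of dynamic elements,
    bias-corrected transcription-factor motif deviation scores with
    synergy and correlation analysis, positive TF regulator matching
    against accessibility-derived gene scores, lineage-fate composition
    binning, and promoter-window PWM scanning for TF-target network
    construction. Ships a synthetic multiome generator with a bifurcating
    trajectory and planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
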