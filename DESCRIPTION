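Package: stemsig
Title: Stemness and Proliferation Signature Analysis for Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble stemness gene signatures from expression
    datasets by multi-dataset selection and intersection, regress out
    consensus tumor purity from log-expression, fit a signature-restricted
    principal-component stemness axis, stratify tumor samples into Stem and
    Normal clusters by median rules, quantify per-tumor signature intensity
    with Wilson confidence intervals, compare cluster survival with Cox
    proportional-hazards models, and project single-cell profiles onto the
    bulk-derived axis. Includes seed-deterministic generators of synthetic
    bulk, survival, and single-cell data with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Matrix,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
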