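Package: ifnscore
Title: Interferon Signature Scoring and Prednisone-Stratified Treatment
    Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the blood type I interferon (IFN) response gene
    signature score from microarray or qPCR expression tables, combines
    platforms by per-gene median-centering, derives DAS28-based treatment
    response labels, and performs empirical ROC analysis with
    specificity-constrained cut-off selection, optionally stratified on
    glucocorticoid (prednisone) use. Includes a seeded synthetic-cohort
    generator that emulates the bimodal IFN signature, dose-dependent
    prednisone suppression of the score, and the association between a
    high genuine score and rituximab non-response, so every pipeline
    stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
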