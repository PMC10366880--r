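Package: tkvqc
Title: Quality Control for MRI-Based Total Kidney Volume Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes left, right and total kidney volume (TKV) from binary
    segmentation mask stacks, screens multi-sequence abdominal MRI exams for
    acquisition errors by inter-sequence outlier analysis, detects and (where
    possible) corrects four classes of geometric acquisition error --
    breathing-motion slice misregistration, breath-hold position mismatch,
    composing overlap between acquisitions, and kidneys truncated by the field
    of view -- and summarises inter-observer and inter-sequence agreement
    (coefficient of variation, pairwise percent differences, Bland-Altman
    limits of agreement, per-sequence bias). A synthetic multi-sequence
    phantom generator with a ground-truth ledger and configurable error
    injection supports end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
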