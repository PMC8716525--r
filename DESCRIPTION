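Package: maskpassage
Title: Size-Resolved Aerosol Passage Evaluation for Filtering Face Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation pipeline for sodium-chloride aerosol filtration tests
    of filtering facepiece respirators (FFP2/FFP3/KN95/N95) measured with a
    laser aerosol spectrometer. Converts size-classed particle counts to
    per-class mass concentrations, computes per-class and mass-weighted total
    particle passage against an unfiltered reference run, validates detector
    equivalence against a flame photometer via Lin's concordance correlation
    coefficient, aggregates per-mask results into batch-level quality
    statistics and compliance verdicts, and categorises batches by their
    size-dependent retention behaviour. A synthetic campaign simulator
    (lognormal test aerosol, size-dependent mask penetration, Poisson
    counting, flame-photometer emulation) makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
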