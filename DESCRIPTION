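Package: proteaseAL
Title: Explainable Active Learning for Serum Protease-Panel Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of fluorescence plate-assay readouts from a
    panel of graphene nanobiosensors that report serum protease activities in
    healthy, localized and metastatic ovarian-cancer cohorts. Provides a
    seeded synthetic-cohort generator, triplicate-well signal processing with
    quality control, variance-gated two-sample testing (F-test gate, Student or
    Welch t-test), two explainable base classifiers (a hierarchical two-stage
    k-nearest-neighbour model and a two-layer linear-activation network) trained
    under pool-based active learning with least-confidence uncertainty
    sampling, exact Shapley feature attribution by coalition enumeration, and
    confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
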