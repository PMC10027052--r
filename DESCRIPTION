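Package: timecellbench
Title: Synthetic Benchmarks and Detection Algorithms for Hippocampal Time
    Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates ground-truth-labeled synthetic two-photon calcium
    imaging datasets for time-cell experiments and benchmarks ten time-cell
    detection algorithms on them. Provides a calcium transient template
    generator and event-library curation from dF/F tensors, a dataset
    synthesizer controlled by 17 parameters (hit trial ratio, event width,
    timing imprecision, noise, Poisson background activity and others) with
    a reference quality score, three detector families (temporal
    information with circular-shuffle bootstrap, ridge-to-background ratio
    with random-offset controls, and parametric-equation estimation) each
    with bootstrap and Otsu threshold classification, and a benchmarking
    layer with confusion metrics, score and prediction correlations, ROC
    analysis, consensus (concordance) classification and
    parameter-sensitivity slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
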