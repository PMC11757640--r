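Package: rnnflow
Title: Information Flow and Weight Importance in Evolved and
    Backpropagated Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains small Elman recurrent networks on an active
    categorical perception task by two optimization methods, a
    generational genetic algorithm and full-batch backpropagation
    through time, and analyses how the trained networks move
    information. Recurrent activity is median-binarized and directed
    information flow is quantified with plug-in transfer entropy from
    sets of source nodes to single target nodes; the functional
    importance of the corresponding recurrent weights is measured by
    sweeping one-sided uniform weight noise and recording relative
    fitness loss. Includes replicate orchestration, paired
    transfer-entropy/importance scans, per-set-size summaries,
    Spearman correlation and weight-distribution comparisons, and
    report generation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
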