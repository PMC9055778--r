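Package: methylvr
Title: Post Hoc Batch-Effect Diagnostics for Infinium-Style Methylation
    Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Probe-wise diagnostics for batch-effect correction of DNA
    methylation array data. Detects multi-modal CpG probes with exact
    optimal univariate k-means clustering under BIC model selection,
    applies an empirical-Bayes location/scale batch corrector (or a plain
    mean-centering corrector) on the M-value scale, and evaluates every
    probe with a cluster-aware log-variance-ratio (LVR) and mean beta-shift
    statistic to classify probes as batch-effect susceptible or erroneously
    corrected. Modal probes are attributed to gender, batch, superbatch and
    cell composition by exact and Monte-Carlo tests, and to allele-specific
    methylation by a Hardy-Weinberg exact test on cluster sizes. Includes a
    synthetic Infinium-like study generator with ground-truth probe
    archetypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
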