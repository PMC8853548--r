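Package: mbnoise
Title: Background-Noise Correction and Benchmarking for Multi-Study Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and remove technical background noise (batch and
    study effects) from compositional microbiome feature tables. Implements
    compositional transforms (closure, pseudocount zero replacement, centered
    log-ratio and its inverse, log counts-per-million), supervised corrections
    (batch mean centering, direct covariate correction, limma-style linear
    batch removal, parametric empirical-Bayes ComBat, percentile
    normalization) and unsupervised principal-component correction with a
    fixed or validation-tuned number of removed components. Ships the two
    benchmark procedures used to compare such corrections: a control-titration
    experiment that measures inflation of false-positive case-control
    associations when control samples are progressively replaced by controls
    from a second study, and leave-one-dataset-out cross-validated phenotype
    prediction with random forests (binary traits) or linear/ridge regression
    (continuous traits). A synthetic multi-study generator with known
    per-feature multiplicative study bias, planted differential features and
    tunable phenotype-study confounding provides ground truth for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    cluster,
    withr,
    jsonlite,
    biomformat,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
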