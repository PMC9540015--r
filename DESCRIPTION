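Package: ebmstage
Title: Event-Based Modelling and Staging of Disease Progression from
    Cross-Sectional Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the most likely ordering in which regional brain
    morphometric measures become abnormal in mesial temporal lobe epilepsy
    with hippocampal sclerosis, from cross-sectional multicenter data, and
    assigns each subject a fine-grained disease stage. Implements the full
    pipeline: a synthetic multicenter cohort generator with a known
    ground-truth event sequence, missing-data filtering and SVD-based
    imputation, empirical-Bayes ComBat harmonization of center biases,
    covariate residualization, ipsilateral/contralateral relabeling and
    brain asymmetry indices, robust effect-size feature selection, a kernel
    density estimation based mixture event-based model fitted by greedy
    ascent and Markov chain Monte Carlo over permutations, bootstrap
    positional variance diagrams, per-subject staging, and stage-clinical
    association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
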