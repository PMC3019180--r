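Package: stemsvm
Title: Kernel-Based Classification of Stem-Cell Self-Renewal Genes from
    Expression and ChIP-Seq Features
Version: 0.1.0
Authors@R:
    person("Huang", "Wei", email = "stemsvm@example.org",
           role = c("aut", "cre"))
Description: Supervised prediction of mouse embryonic stem cell
    self-renewal and pluripotency membership genes (MSMGs) from
    heterogeneous genomic data.  Builds per-gene feature vectors from
    expression time courses (79 conditions) and transcription-factor
    ChIP-seq peaks (12 factors, binary presence or distance-decay
    binding scores), trains soft-margin support vector machines on
    precomputed linear, polynomial, Gaussian and F1-weighted multi-type
    kernels, evaluates them by leave-one-out cross-validation and
    three-fold ROC/AUC, ranks features by SVM recursive feature
    elimination, and prioritizes RNAi-screen hits by a signal-to-noise
    enrichment ratio.  Ships a synthetic-data generator emulating the
    study layout so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    limma,
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
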