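Package: bnaf
Title: Antifragility, Robustness and Evolvability of Boolean Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("bnaf", "developers", email = "bnaf@example.org", role = c("aut", "cre"))
Description: Tools for synchronous Boolean network models of gene regulation:
    exhaustive attractor and basin-of-attraction enumeration, four elementary
    structural mutations (link addition, deletion, rewiring, truth-table bit
    flips), classification of mutants into four robustness/evolvability
    classes by attractor-set comparison, Shannon-entropy based
    emergence/complexity measures, an external-perturbation protocol yielding
    fragility/antifragility curves, and a small 1-D convolutional neural
    network pipeline (SMOTE/ADASYN oversampling, nested k-fold
    cross-validation, precision-recall evaluation) that predicts the
    robustness/evolvability class of a mutation from the antifragility
    difference curve alone.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
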