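Package: refstab
Title: Reference-Gene Stability and Consensus Ranking for RT-qPCR
Version: 0.1.0
Authors@R: person("refstab", "maintainers", email = "refstab@example.org",
    role = c("aut", "cre"))
Description: Tools to select stable reference (housekeeping) assays for
    RT-qPCR normalization. Implements the geNorm expression-stability
    family (pairwise variation, M-value, stepwise-exclusion ranking,
    geometric-mean normalization factors and the sequential V-value
    criterion with the 0.15 cutoff), and cross-experiment consensus
    ranking of weighted gene lists by Borda count, exhaustive search, or
    cross-entropy Monte Carlo minimization of a weighted Spearman
    footrule distance with M-values as weights. Ships a published
    19-experiment x 11-assay M-value table as a fixture and a synthetic
    qPCR data generator with a closed-form expected-M oracle, so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
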