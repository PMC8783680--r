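Package: trajomics
Title: Temporal Trajectory Classification for Perturbation-Withdrawal Multiomics
Version: 1.0.0
Authors@R: person("trajomics", "maintainers", email = "maintainers@trajomics.dev",
    role = c("aut", "cre"))
Description: Analysis pipeline for three-condition perturbation-withdrawal
    experiments (untreated baseline, treatment, post-withdrawal) in bulk
    proteomics, transcriptomics and metabolomics. Computes the three pairwise
    differential-expression contrasts (Student t-test or imported caller
    output, with Benjamini-Hochberg adjustment), classifies each molecule
    into one of ten temporal trajectory clusters (five response patterns,
    progressive / persistent / partially reversed / completely reversed /
    overcorrection, in two directions), partitions differentially expressed
    molecules across Venn regions and reference gene-set collections
    (GMT format, with optional tissue tags), performs right-tailed Fisher
    exact gene-set enrichment, and scores concordance between the supervised
    cluster labels and unsupervised k-means/hierarchical clustering via the
    adjusted Rand index. Includes a synthetic-data generator with known
    per-molecule trajectory truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
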