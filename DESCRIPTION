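Package: accumap
Title: Transcriptome-Only Subtype Discovery for Adrenocortical Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis workflow for unsupervised molecular subtype
    discovery from bulk RNA-seq FPKM matrices, built around three stages:
    a from-first-principles UMAP variant (entropy-calibrated per-sample
    bandwidths, mean-symmetrized fuzzy graph, normalized-Q cross-entropy
    minimized by full-batch gradient descent), a stability-selection-style
    consensus ranking of marker genes over many random-forest classifiers
    trained on independent 50/50 splits, and downstream survival
    (Kaplan-Meier, log-rank, univariate Cox) and mutation/expression
    association statistics (Kruskal-Wallis). Includes a synthetic-cohort
    generator with planted cluster structure, cluster-dependent survival
    and mutation frequencies, so that every stage is testable without
    access to patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    ranger,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
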