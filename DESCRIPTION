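Package: sctme
Title: Single-Cell Tumor Microenvironment Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dissecting tumor microenvironments from
    droplet single-cell RNA-seq: quality control and normalization, graph-based
    clustering and curated-set cell-type annotation, simulated-doublet scoring
    with iterative cluster-based removal, copy-number inference from smoothed
    expression profiles with malignant-cell classification against a normal
    reference, per-tumor non-negative matrix factorization with cross-tumor
    consolidation of malignant expression signatures, rule-based immune
    subcluster marker signatures, single-sample gene set enrichment scoring of
    bulk cohorts with Kaplan-Meier and Cox survival association, and
    permutation-based ligand-receptor interaction testing. Includes a
    synthetic-data generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    survival,
    igraph,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
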