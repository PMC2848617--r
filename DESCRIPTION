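Package: appia
Title: Integrated Prediction of Protein Functional Associations from
    Evolutionary Signals
Version: 1.0.0
Authors@R:
    person("Ana", "Ribeiro", email = "ana.ribeiro.dev@gmail.com",
           role = c("aut", "cre"))
Description: Combines five evolutionary protein-protein association
    predictors (phylogenetic profiles, gene-context conservation, gene
    fusion, mirror tree and in silico two-hybrid) into a single
    probabilistic classifier based on Averaged One-Dependence Estimators
    (AODE). Provides readers for ortholog tables, gene coordinates,
    ortholog alignments and pair lists; assembly of 19-attribute
    instances with protein-centered rank attributes; gold-standard and
    balanced train/test set construction; equal-frequency discretization
    and an AODE implementation with known-values-only missing-data
    semantics; and classifier assessment with ROC curves, cost curves
    (lower-envelope construction), Matthews correlation and top-n
    accuracy of ranked prediction lists. A synthetic world generator
    with plantable signals for each predictor makes the full pipeline
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
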