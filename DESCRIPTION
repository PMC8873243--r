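Package: srnet
Title: Structurally Resolved Interaction Networks and Edgetic Mutation Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structurally resolved protein-protein interaction networks
    in which every interaction carries the interface residues that mediate it,
    annotates residues as core, surface or interface from relative solvent
    accessibility, and models missense mutations as edgetic perturbations:
    removal of the interaction edges a mutated residue maps to. Provides seven
    protein-level centrality features and nine residue-level perturbation
    features for variant classification, a random-forest training and
    evaluation framework with gene-holdout cross-validation, enrichment and
    ROC-comparison statistics (Fisher odds ratios, Mann-Whitney tests, DeLong
    test), and seeded synthetic-data generators with planted signal for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    data.table,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readxl,
    jsonlite
Config/testthat/edition: 3
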