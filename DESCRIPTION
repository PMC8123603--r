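Package: smpd1zoom
Title: Three-Class Severity Classification of SMPD1 Missense Variants
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification of missense variants in acid sphingomyelinase
    (SMPD1) into Niemann-Pick disease type A, type B and neutral classes
    with a k-nearest-neighbour model built on standardized sequence-,
    stability- and structure-based features. Includes harmonization of
    variant annotations from multiple sources, extraction of residue
    interactions (disulfide bridges and pi-pi, cation-pi, amino-pi,
    His-pi and sulfur-pi contacts) and residue environments from protein
    structures, ANOVA/Chi-squared feature selection, position-level
    leave-one-out evaluation with balanced accuracy and one-vs-rest
    AUROC, saturation mutagenesis scans, genotype-level prediction for a
    recessive disease, and non-linear curves linking class probabilities
    to measured relative enzymatic activity. A synthetic-fixture module
    generates feature tables, toy structures, genotypes and activity
    data so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
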