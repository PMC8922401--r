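Package: dtalearn
Title: Drug-Target Binding Affinity Modelling with Contextual Sequence
    Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting drug-target binding affinity (DTA) from
    compound SMILES strings and protein amino-acid sequences.  Provides
    character- and atom-level tokenizers with fixed-length padding, a
    miniature replaced-token-detection (generator/discriminator)
    pretrainer for contextual sequence encoders, squeeze-and-excitation
    convolutional feature extractors with highway-gated regression for
    affinity prediction, the standard DTA evaluation panel (concordance
    index, mean squared error, Pearson correlation, the r_m^2 external
    validation index, and AUPR by affinity thresholding), dataset
    refinement for duplicated and conflicting affinity records, and
    similarity-cluster based cold-drug, cold-target and blind
    train/validation/test splits built on normalized Smith-Waterman and
    Morgan-fingerprint Jaccard distances.  Seeded synthetic generators
    for corpora, sequence families and planted-signal affinity tables
    make the whole pipeline testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
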