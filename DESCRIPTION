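Package: lysmod
Title: Multi-Label Prediction of Concurrent Lysine Post-Translational Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts concurrent post-translational modifications (acetylation,
    crotonylation, methylation, succinylation) at single lysine residues from
    protein sequence. Implements 49-residue lysine-centered peptide windowing,
    multi-label position-specific triad amino-acid propensity (MLPSTAAP)
    feature encoding, cluster-centroid majority-class undersampling driven by
    mini-batch k-means, a small one-dimensional convolutional multi-label
    classifier trained with binary cross-entropy, and the five set-based
    multi-label evaluation metrics (Aiming, Coverage, Accuracy, Absolute-True,
    Absolute-False) with per-category exact-match breakdowns, stratified
    cross-validation and an undersampling-ratio sweep harness. A seeded
    synthetic-data generator with planted position-specific triad motifs makes
    the whole pipeline testable without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
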