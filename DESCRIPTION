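Package: DNABindProfiles
Title: DNA-Binding Protein Prediction from Evolutionary and Structural
    Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a protein binds DNA from two per-residue
    profiles: the position-specific scoring matrix (PSSM) produced by
    iterative profile search (PSI-BLAST) and the predicted-structure
    profile (secondary structure, accessible surface area, backbone
    torsion angles and structure-class probabilities) produced by the
    SPIDER family of predictors. Fourteen formula-defined feature blocks
    (composition, lagged bigram, auto-covariance, segmented distribution,
    CTD descriptors and consensus-sequence composition) are concatenated
    into a 1546-dimensional vector, reduced by recursive feature
    elimination under a linear maximum-margin ranker, and classified with
    a support vector machine. Jackknife and repeated stratified k-fold
    evaluation with sensitivity, specificity, accuracy, Matthews
    correlation and ROC/PR areas are included, together with parsers and
    writers for the PSSM and SPD3 text dialects and a synthetic profile
    generator for end-to-end testing without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
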