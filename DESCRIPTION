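Package: nucsig
Title: Nuclear Protein Localization Prediction from Gapped-Dipeptide
    Signatures
Version: 0.1.0
Authors@R:
    person("nucsig", "developers", email = "nucsig@example.org",
           role = c("aut", "cre"))
Description: Predicts nuclear versus non-nuclear protein subcellular
    localization from sequence alone.  Proteins are encoded as
    gapped-dipeptide "words" weighted by smoothed, logistic-normalized
    position-specific scoring matrix (PSSM) profiles; the resulting
    weighted bag-of-words corpus is reduced with probabilistic latent
    semantic indexing (PLSI, an aspect model fitted by EM with
    folding-in for unseen proteins) and classified with an RBF-kernel
    support vector machine.  Localization-preferred PLSI topics yield
    interpretable gapped-dipeptide signatures for putative nuclear
    localization and export signals, which can replace the topic
    features in a compact signature-based classifier.  Includes a
    deterministic synthetic-data generator with planted NLS/NES-like
    motifs, a cross-validation harness with confusion-count metrics
    (sensitivity, specificity, accuracy, MCC), and a command-line
    pipeline.  No database search is required: when PSI-BLAST profiles
    are unavailable a BLOSUM62 pseudo-profile is substituted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
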