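Package: tpwm
Title: Tree-Based Position Weight Matrices for Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models intra-motif position dependencies in transcription
    factor binding sites with tree-based position weight matrices (TPWMs):
    rooted trees whose internal nodes partition aligned sites by the
    nucleotide at a maximal dependent position and whose leaves carry
    conditional position weight matrices.  Implements the TPD
    discriminative training loop, which refines an initial TRANSFAC- or
    JASPAR-style matrix against a positive and a negative sequence set
    over a grid of false positive rates and selects the model with the
    largest Matthews correlation coefficient.  Includes log-odds motif
    scanning, a Markov-background motif-implantation simulator with
    position-correlated motif models and Fisher-Yates shuffled negatives,
    and evaluation utilities (pattern prediction accuracy, ROC/AUC on
    best-hit scores, information content).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
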