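Package: disbrnn
Title: Prediction of Short Intrinsically-Disordered Protein Regions with
    Two-Stage Bidirectional Recurrent Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-residue prediction of short intrinsically-disordered
    regions (runs of 3-30 consecutive disordered residues) in protein
    chains. Implements a two-stage bidirectional recurrent neural network
    sequence labeller: forward and backward hidden-state chains with a
    configurable shortcut span feed a per-position output network, and a
    second-stage filter network consumes window-averaged first-stage
    predictions over a wide semi-global context. Four input encodings are
    supported: amino-acid frequency profiles from multiple sequence
    alignments (21 channels including gaps), predicted three-class
    secondary structure, four-class solvent accessibility, and
    cubed-identity-weighted order/disorder annotations transferred from
    homologous template structures. Includes cross-entropy training by
    gradient descent with backpropagation through structure, learning-rate
    halving, checkpoint ensembling, five-fold cross-validation, chain
    filtering and redundancy reduction, a full evaluation suite (ROC/PR
    curves and AUCs, MCC, balanced accuracy, FPR-anchored thresholding,
    termini trimming, template-identity-binned AUC), a synthetic-corpus
    generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
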