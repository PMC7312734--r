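Package: ppiwave
Title: Sequence-Based Protein-Protein Interaction Prediction with
    Wavelet Features and a Weight-Shared Bidirectional LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interactions from primary sequence
    alone. Each protein is digitized into eight physicochemical signals
    (hydrophobicity, hydrophilicity, side-chain volume, polarity,
    polarizability, solvent-accessible surface area, net charge index and
    a composite isoelectric-point/pKa property), summarised by a four-level
    discrete Meyer wavelet decomposition and the singular values of a
    25-scale Mexican-hat continuous wavelet transform into a 600-dimensional
    descriptor. Protein pairs are classified by a two-branch ("Y-type")
    bidirectional LSTM in which both branches share one set of weights, with
    forward/backward pair-order augmentation of the training set. Includes a
    synthetic-data generator with planted interaction structure, stratified
    cross-validation, confusion-matrix metrics (accuracy, recall,
    specificity, precision, MCC) and rank-based AUC, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
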