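Package: pgact
Title: Prediction of Plasminogen Activators and Their Subfamilies from
    Sequence Composition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-composition toolkit for recognising plasminogen
    activators (the fibrinolytic proteases and cofactors that convert
    plasminogen to plasmin) and assigning them to the staphylokinase (SAK),
    streptokinase (SK), tissue plasminogen activator (tPA) or urokinase (UK)
    subfamily. Protein sequences are encoded as amino-acid composition
    (20-dimensional), dipeptide composition (400), PSSM-profile composition
    (400) or hybrid (420) feature vectors and classified with radial-basis
    soft-margin support vector machines trained by a built-in SMO solver.
    Includes a two-stage hierarchical predictor (activator versus
    non-activator, then one-vs-rest subfamily assignment), a five-fold
    cross-validation harness with accuracy/sensitivity/specificity/MCC and
    ROC analysis, a CD-HIT-style greedy redundancy filter, per-sequence
    statistics (molecular weight, residue counts, composition), a seeded
    synthetic protein-family generator for offline benchmarking, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
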