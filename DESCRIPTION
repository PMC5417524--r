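Package: mascan
Title: Prediction of Matrix-Protein Boundaries in Retroviral Gag Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the exact start and end coordinates of the matrix
    protein (MA) inside endogenous-retrovirus gag amino-acid sequences.
    Independent 15-residue initiation-site and termination-site classifiers
    are trained over a hybrid feature space combining position-weight-matrix
    log-likelihood scores with ten physicochemical amino-acid property
    scales.  Candidate boundary sites called by random-forest models are
    paired under an MA length constraint (88 to 127 residues) and the final
    prediction is selected by a weighted-SVM veto plus a maximum
    decision-value-product rule.  Includes weighted extreme learning
    machines, grid-search tuning, G-mean/MCC cross-validation harnesses, a
    planted-motif synthetic corpus generator, six-frame DNA scanning, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
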