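Package: trimorf
Title: MoRF Prediction by Trisecting Disordered Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts molecular recognition features (MoRFs) in
    intrinsically disordered protein sequences. Each sequence is split
    into terminal and middle zones and residues are scored by two
    support vector machines trained on auto-covariance features of
    predicted structural attributes (half-sphere exposure by default).
    Raw score tracks are smoothed with a windowed (max + median)/2 rule
    and tracks from several predictors can be fused by averaging.
    Includes per-residue ROC/AUC evaluation, a synthetic-data generator
    so the full train/predict/evaluate pipeline runs without external
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
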