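Package: wristpd
Title: Digital Motor-Symptom Indicators from Wrist Accelerometry in Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline analysis pipeline for labeled triaxial wrist-accelerometer
    recordings of standardized Parkinson's disease motor exercises. Provides a
    synthetic-cohort simulator with severity-linked tremor and bradykinesia signal
    models, a delimited-text session format with run-length exercise labeling,
    Butterworth high-pass gravity removal and Euclidean-norm computation, per-segment
    time- and band-power features plus a sliding-window activity-recognition feature
    set, band-power thresholding for continuous resting-tremor interval labeling, and
    a statistical surface of Pearson feature-versus-MDS-UPDRS correlations and t-SNE
    embeddings brushed by clinical severity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    Rtsne,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
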