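Package: ecgwolf
Title: Arrhythmia Classification from ECG with Gray-Wolf Feature Selection and an LSTM Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for five-class ECG arrhythmia
    classification: min-max normalization, zero-phase band-pass filtering,
    heartbeat segmentation, formula-defined feature extraction (segment
    energy, summary statistics, wavelet sub-band energies, 1-D gray-level
    co-occurrence texture), wrapper feature selection by an enhanced binary
    gray wolf optimizer with stratified K-nearest-neighbour cross-validation
    fitness, a from-scratch LSTM classifier trained with Adam, and a full
    evaluation suite (confusion matrix, per-class sensitivity/specificity,
    one-vs-rest ROC/AUC, error histogram, McNemar model comparison). A
    seeded synthetic five-class ECG generator makes every stage testable
    without external data; WFDB and CSV readers support real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
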