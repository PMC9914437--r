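Package: eegaudiometry
Title: Automatic Pure-Tone Audiometry from EEG with Text-Style Signal Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an adaptive random pure-tone hearing test whose
    heard/unheard outcomes are decoded from simultaneous 16-channel EEG.
    Provides the adaptive stimulus-pruning protocol and audiogram
    computation, a synthetic P300 event-related-potential EEG generator,
    BrainVision (.vhdr/.vmrk/.eeg) readers and writers, notch/band-pass
    preprocessing, marker-based epoch labeling, a count-vectorizer plus
    TF-IDF encoding that treats rounded sample values as words, and a
    seven-classifier evaluation harness with confusion-matrix metrics,
    ROC/AUC, log loss, cross-validation and channel-ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    class,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Matrix,
    optparse
Config/testthat/edition: 3
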