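Package: sleepatt
Title: Hybrid Channel- and Time-Wise Attention Networks for Multivariate
    Sleep Stage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end deep learning toolkit for classifying sleep
    stages from multivariate polysomnography (PSG) records. Heterogeneous
    channels (EEG, EOG, EMG, ECG at mixed sample rates) are segmented into
    labelled 30-second epochs and encoded by a multi-view convolutional
    module: one 1-D max-pooling encoder per channel plus a 2-D
    average-pooling encoder over the aligned channel matrix. A hybrid
    self-attention mechanism fuses the channel-view and global-view
    features through a learned sigmoid fusional rate, feeds the fused
    sequence through a two-layer bidirectional GRU, and attends over time
    to build a per-epoch context vector; a softmax head predicts one of
    five sleep stages. Training (Adadelta with L2 penalty and dropout),
    subject-independent cross-validation, the five standard evaluation
    metrics, a seeded synthetic PSG cohort generator, STFT frequency-domain
    features, and a command-line interface are included. All forward and
    backward computations run on a small built-in reverse-mode
    differentiation tape, so the package has no deep-learning framework
    dependency.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
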