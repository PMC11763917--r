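Package: timeArrow
Title: Arrow-of-Time Self-Supervised Pretraining and Saliency Analysis for
    Multivariate Neural Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Self-supervised pretraining of recurrent attention classifiers
    on multivariate time courses (for example ICA time courses from
    resting-state fMRI) via the time-reversal pretext task: a model learns to
    distinguish forward from time-reversed sequences, and the learned weights
    transfer to downstream binary classification of small clinical cohorts.
    Includes an LSTM/GRU encoder with concatenation attention and dropout
    decoder implemented with hand-derived backpropagation, Adam training with
    plateau scheduling and early stopping, stratified cross-validation,
    order-contrastive and permutation-contrastive pretraining baselines,
    synthetic chirp and episodic-disease cohort generators, and an
    explainability toolkit: integrated-gradients saliency maps,
    forward/reverse flip-alignment correlation, top-fraction masking,
    time-marginal distributions, an Earth Mover's Distance spikiness
    statistic, and submodular pick of representative subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
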