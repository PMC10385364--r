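Package: tugfall
Title: Fall-Risk Assessment from Waist-Worn Inertial Recordings of an
    Instrumented Timed Up and Go Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes six-axis inertial recordings (3-axis accelerometer,
    3-axis gyroscope, nominally 100 Hz) of a modified Timed Up and Go
    protocol recorded at the waist: uniform resampling, zero-lag Butterworth
    filtering, complementary-filter orientation estimation, frequency-domain
    double integration to centre-of-mass displacement, segmentation of the
    protocol phases, and extraction of ten balance, gait and functional
    features. Includes test-retest reliability statistics (two-way
    random-effects intraclass correlation, group t-tests, assumption
    checks), a bank of fifteen feature-based classifiers with recursive
    feature elimination and repeated stratified cross-validation, a
    two-branch convolutional + LSTM network over raw signal windows and
    their log-spectrograms, and a synthetic-trial simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    MASS,
    nnet,
    class,
    rpart,
    e1071,
    randomForest,
    glmnet,
    xgboost,
    car
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
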