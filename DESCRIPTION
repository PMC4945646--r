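Package: physioad
Title: Multimodal Physiological Features and Classifier Protocols for
    Rating Audiovisual Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the emotional effectiveness of short
    audiovisual stimuli (TV commercials) from multimodal physiological
    recordings. Implements a synthetic session generator (EEG, single-lead
    ECG, galvanic skin response, respiration with class-conditional
    structure), signal preprocessing (EEG kurtosis quality control,
    channel interpolation, epoching, ICA-based blink removal; ECG
    filtering; morphological smoothing of electrodermal and respiratory
    traces), feature batteries (global field power and baseline z-score
    EEG metrics, Welch band power, a 56-metric heart-rate-variability
    battery built on Pan-Tompkins QRS detection, skin-conductance peak
    features, respiration features), and a staged classification protocol
    (SMOTE balancing, standardization, wrapper feature selection, and
    cascades of multiclass/boosting/bagging meta-classifiers over random
    forests under stratified cross-validation) that labels stimuli as
    positive, neutral or negative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    class,
    e1071,
    foreign,
    nnet,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
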