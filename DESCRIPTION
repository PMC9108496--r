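Package: emofc
Title: Region-Specific EEG Emotion Recognition and Dynamic Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying music-evoked emotional
    states (high vs. low valence-arousal) from multichannel EEG. Provides a
    synthetic EEG generator with analytically controlled inter-channel
    coherence and planted class-discriminative oscillatory power; standard
    preprocessing (notch and bandpass filtering, common average reference,
    baseline correction, trial segmentation); per-second EEG-to-image
    encoding for a compact depthwise-separable convolutional classifier
    trained under fivefold cross-validation; sequential backward selection
    over frontal channels; and magnitude-coherence functional connectivity
    with dynamic trial-concatenated features and Fisher r-to-z paired
    comparison between emotion states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
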