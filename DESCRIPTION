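Package: fogdetect
Title: Detecting Freezing-of-Gait Episodes from Subthalamic Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting freezing-of-gait (FOG) episodes
    from bilateral subthalamic-nucleus local field potential (LFP) recordings.
    Includes a seeded synthetic LFP cohort generator with ground-truth FOG events,
    spectral feature engineering (derived bipolar channels, canonical and
    participant-specific band powers, rolling statistics, alpha-beta burst
    dynamics), windowed labelling, a sequence classifier combining convolutional,
    transformer, cross-attention and bidirectional GRU components trained with
    focal loss and adapted per trial by transfer learning, leave-one-trial-out
    cross-validation with timepoint- and event-level evaluation, and
    channel-grouped gradient Shapley attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
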