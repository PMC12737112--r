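Package: emofuse
Title: Late-Fusion Multimodal Emotion Recognition from Wearable Biosignals
    and Facial Expression Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete pipeline for frame-level emotion recognition in
    therapy-session recordings that combine wristband biosignals
    (electrodermal activity and skin temperature at 4 Hz, heart rate at
    1 Hz) with a facial-analysis dominant-emotion event log and three
    human annotator tracks.  Annotations are aggregated under two schemes
    (per-second majority-vote labels and proportional emotion
    distributions), streams are synchronized on a common 1 Hz clock,
    standardized per subject, and segmented into overlapping 4-second
    windows.  Per-modality bidirectional LSTM sequence models with masked
    losses are trained on subject-disjoint splits with minority-class
    upsampling from native-rate data, and combined by decision-level
    fusion: multinomial logistic regression for categorical labels and a
    recurrent weighted fusion network for emotion distributions.  Includes
    the full evaluation suite (balanced accuracy, micro and macro
    precision, recall and F1, Hamming loss, per-emotion MSE, MAE and
    cosine similarity, confusion matrices, dominant-emotion mapping) and
    a seeded synthetic session generator so every stage is testable
    without access to private recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
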