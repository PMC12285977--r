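Package: gazehmm
Title: Hierarchical GMM-HMM Ternary Eye-Movement Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Per-sample classification of gaze recordings into fixation,
    smooth pursuit and saccade events with a hierarchical Gaussian mixture
    model hidden Markov model (GMM-HMM): a k-means sum-of-squared-errors
    elbow rule segments the gaze path, a first-round spatial GMM-HMM splits
    the recording into coherent segments, and a second-round velocity
    GMM-HMM labels each segment. Includes threshold and Bayesian baseline
    classifiers (I-VT, I-VDT, I-BDT), per-class evaluation metrics, a
    seeded synthetic gaze-trajectory generator, and a hardware-free
    gaze-to-robot coordinate chain with trajectory-smoothness metrics
    (curvature, angular variation rate) for gaze-guided manipulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
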