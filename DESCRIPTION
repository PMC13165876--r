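Package: gazecog
Title: Multimodal Eye-Tracking and Facial-Expression Screening of Cognitive Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for screening cognitive decline from multimodal behavioral
    recordings collected during five gamified assessment paradigms. The package
    reads and validates synchronized eye-tracking (binocular origins, merged
    gaze point, pupil diameters, eye openness) and facial blend-shape time
    series, repairs blink artifacts, filters pupil traces with a causal
    second-order Butterworth recursion, segments gaze into fixations and
    saccades with the I-VDT algorithm, and computes 27 formula-defined
    behavioral features spanning visual search, memory calculation, pupillary
    light reflex, pro-/anti-saccade, and facial emotion expression tasks. A
    multi-task multi-stream parallel convolutional network (MT-MSPCNN) with
    sliding-window multiple-instance learning, gated attention pooling, and
    majority-vote decision fusion classifies subjects as healthy controls or
    cognitively declined; classical baselines (logistic regression, Gaussian
    naive Bayes, RBF support-vector machines) and Mann-Whitney group statistics
    are included, together with a synthetic cohort generator that emulates the
    study conditions so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
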