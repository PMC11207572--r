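Package: vepdecode
Title: Discriminant Channel Selection and Compact Deep Classifiers for
    Visual EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decoding visually evoked potentials from
    multichannel EEG into many stimulus classes with a reduced electrode
    montage. Implements mutual-information-based discriminant channel
    selection from histogram entropy estimates, an evoked-response
    enhancement chain (bad-channel repair, artifact span rejection,
    per-channel standardization, epoching, evoked averaging over nine
    canonical post-stimulus windows), declarative builders with exact
    parameter accounting for two compact classifiers (a temporal/
    depthwise/separable convolutional network and a hybrid
    convolutional-recurrent network), a cyclical-learning-rate training
    loop with k-fold and leave-one-subject-out evaluation protocols, and
    a synthetic generator that emulates a 6-subject, 40-class, 128-channel
    visual EEG corpus with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
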