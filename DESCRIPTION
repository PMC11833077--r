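Package: ecgsaliency
Title: Jacobian Saliency Maps for Domain-Adversarial 12-Lead ECG Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pixel-level interpretability for convolutional classifiers of
    12-lead electrocardiogram (ECG) raster images. Implements a
    domain-adversarial network (convolutional feature extractor, transposed
    convolution signal decoder, label predictor, and domain classifier joined
    by a gradient reversal layer), a three-phase training procedure with a
    dynamic gradient-reversal schedule, and per-pixel Jacobian sensitivity
    maps for both the presence and absence of a cardiac condition. Ships a
    synthetic 12-lead ECG generator that renders parametric waveforms
    (bradycardia, tachycardia, atrial fibrillation, atrial flutter, wide-QRS
    morphologies, premature ventricular complexes) onto checkered ECG paper
    with exact signal-pixel masks, a mobile-photo artifact simulator
    (shadows, perspective, flash saturation, coupled blur), blur and
    segmentation preprocessing gates, and an agreement coefficient for
    scoring saliency masks against expert annotation masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jpeg,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
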