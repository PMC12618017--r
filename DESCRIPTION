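Package: vshortr
Title: Virtual Short-Separation Channels for fNIRS Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts short-separation optical-density signals from
    long-separation functional near-infrared spectroscopy (fNIRS) channels
    with a small transformer encoder, and uses the predicted "virtual short
    channels" as regressors to remove superficial (scalp) physiology from
    long-channel recordings.  Includes a seeded multichannel physiological
    signal simulator (cardiac, respiratory and Mayer-wave oscillations with
    spatially heterogeneous scalp coupling), wavelet-coherence channel
    quality control, window segmentation and normalisation, the hybrid
    mean-squared-error plus Pearson-correlation training loss, AdamW
    optimisation with cosine annealing, test-time augmentation, montage
    adaptation by projection-layer transfer, short-channel regression,
    zero-phase band-pass filtering, modified Beer-Lambert conversion to
    hemoglobin concentration changes, block averaging of task responses and
    the associated evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
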