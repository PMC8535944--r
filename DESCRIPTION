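Package: heartkit
Title: Heart-Sound Segmentation, Spectrogram Features and Murmur Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A phonocardiogram (PCG) analysis toolkit for screening heart-sound
    recordings. Recordings are denoised with zero-phase IIR filtering, cut into
    single cardiac cycles using a Daubechies-wavelet Shannon-energy envelope and
    unbiased-autocorrelation period estimation, converted to mel-frequency
    cepstral (MFCC) spectrogram images, screened for noisy cycles by
    two-component Gaussian-mixture clustering fitted with expectation
    maximization, and classified as normal, murmur or extrasystole under a
    stratified, recording-grouped k-fold protocol with per-class and micro
    sensitivity, precision and specificity. A deterministic synthetic PCG
    generator with ground-truth beat annotations makes the full pipeline
    testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nnet,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
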