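Package: mwstroke
Title: Multimodal Microwave Imaging Pipeline for Hemorrhagic Stroke Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end synthetic pipeline for microwave-based hemorrhagic
    stroke identification. Generates randomized dielectric head phantoms with
    elliptical hemorrhagic inclusions, simulates multistatic time-domain
    microwave acquisition with a 2-D finite-difference time-domain solver on
    the antenna-array plane, reconstructs adaptive confocal microwave images
    from whitened differential spectra, preprocesses paired waveform-image
    samples, trains a dual-branch residual-CNN / 1-D CNN-LSTM fusion
    classifier, and evaluates it with bootstrap confidence intervals and
    paired resampling significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
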