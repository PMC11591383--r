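Package: foldear
Title: Acoustic Recognition of Sheep Feeding Behavior from Barn Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies short barn-audio segments into sheep feeding
    behaviors (foraging, rumination, other) by fusing hand-crafted
    acoustic features with deep features taken from the fully connected
    layers of a shallow convolutional network trained on spectrogram
    images. Provides WAV input/output and energy-based segmentation,
    short-time Fourier, constant-Q and mel spectrograms rendered as
    fixed-size color images, a 68-dimensional acoustic feature extractor,
    SVM recursive feature elimination with cross-validation, the
    SheepVGG-Lite network with EigenCAM interpretability maps, early
    feature fusion with a grid-searched support vector machine, and a
    seeded synthetic sheepfold-audio generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
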