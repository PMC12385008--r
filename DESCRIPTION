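Package: eegstress
Title: EEG Mental-Stress Detection with Wavelet-Packet Features, Crow-Search
    Channel Selection and a Hybrid Deep Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end framework for two-class (calm versus stress)
    mental-state detection from multi-channel EEG. Implements FIR band-pass
    filtering and wavelet-packet soft-threshold denoising, a 527-per-channel
    multiple-EEG-feature extractor (time-domain, wavelet-packet subband,
    spectral and 1-D texture descriptors), channel selection by an improved
    crow search algorithm with Levy-flight elite learning and worst-member
    replacement, a hybrid classifier combining a 1-D deep convolutional
    network, a bidirectional LSTM and a deep belief network trained by
    mini-batch gradient descent, and an employee optimization algorithm for
    hyper-parameter tuning. Includes a seeded synthetic EEG generator
    emulating the band-power structure the method assumes, plus readers for
    delimited-text recordings with the valence/arousal labeling rule used
    for the DEAP benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    e1071,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
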