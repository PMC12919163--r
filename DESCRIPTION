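Package: flashvep
Title: Single-Trial Detection of Microperimetry Flash Stimuli from Occipital EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing whether isolated 200-ms microperimetry flash
    stimuli can be detected from short occipito-parietal EEG recordings on a
    single-trial basis. Provides a ground-truthed synthetic generator of
    flash-evoked EEG (1/f background, alpha activity, common-mode artifacts,
    Gaussian-component evoked responses with occipital-dominant topography and
    configurable synchronization jitter), the preprocessing chain of common
    median re-referencing, 4-49 Hz order-4 Butterworth band-pass filtering and
    per-channel z-score normalization, offset-locked 600-ms segmentation into
    stimulus and non-stimulus epochs, a stacked two-layer bidirectional LSTM
    classifier trained with ADAM, imbalance-aware evaluation (accuracy,
    precision, sensitivity, specificity, F1, Cohen's kappa) with confusion-
    matrix reconstruction from printed metric triplets, and orchestration of
    end-to-end trials and electrode-montage comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
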