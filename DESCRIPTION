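Package: audsal
Title: Auditory Salience Analysis with Audio CNN Layer Activations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating the layer activations of a VGG-style audio
    classification network to acoustic features, behaviorally measured
    auditory salience, and EEG band energies.  Implements the network
    surprisal metric (Euclidean distance between current layer activity and
    its recent history), a common signal-conditioning chain (10 Hz
    resampling, onset trimming, 1/30-1/6 Hz Butterworth band limiting),
    maximum lagged normalized cross-correlation, cumulative variance
    explained by sequential residual regression across layers, and salient
    event prediction with cross-validated linear discriminant analysis and
    ROC curves.  A synthetic study generator produces audio scenes with
    planted salient events, simulated listener attention curves, and
    EEG-like band-energy channels with planted lagged correlations, so that
    every stage of the pipeline has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
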