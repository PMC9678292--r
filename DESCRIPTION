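Package: dnfilt
Title: Real-Time Deep Neural Filtering for Adaptive Noise Cancellation in Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-by-sample adaptive noise cancellation for two-channel
    biosignal recordings, built around a deep neural filter: a funnel-shaped,
    bias-free tanh network that learns online (backpropagation on every
    sample) to synthesize a "remover" signal from a noise-reference channel,
    which is subtracted from the contaminated channel by destructive
    interference.  Ships the causal conditioning chain (Butterworth high-pass,
    50 Hz notch, gain), LMS-adaptive FIR and surface-Laplacian baseline
    filters, a Welch band-power / P300 evoked-potential SNR evaluation
    protocol, and a synthetic compound-electrode EEG/EMG session generator
    with full ground truth, so the whole pipeline is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
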