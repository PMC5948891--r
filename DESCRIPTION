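Package: pedalbci
Title: Online Brain-Computer Interface for Pedaling Motor Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting pedaling motor imagery versus relaxation from
    multichannel EEG in a sliding-window online setting. Implements a cue-based
    experimental protocol with randomized task schedules, a synthetic EEG
    generator with controllable mu-band event-related desynchronization (ERD),
    a preprocessing chain (Butterworth high-pass and low-pass, 50 Hz notch,
    surface Laplacian re-referencing, motor-electrode selection), Burg
    autoregressive power spectra with per-electrode optimal-frequency feature
    selection, RBF-SVM online classification with real-time accuracy and
    feedback accounting, and ERD matrices with mu-band motor-cortex summaries
    and optimal-frequency band histograms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
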