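Package: emdmouse
Title: Hands-Free Mouse Signal Processing with Empirical Mode Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing toolkit for a gyroscope-and-blink hands-free
    computer mouse built on consumer EEG headsets. Implements empirical mode
    decomposition (EMD) with cubic-spline envelopes and Cauchy-type sifting
    stops, suppression of head-movement artifacts by gating intrinsic mode
    functions that correlate across electrodes, double-blink detection from
    IMF-energy features with a Mahalanobis-distance classifier (plus a
    Daubechies-2 wavelet comparison extractor and ROC evaluation), and a
    constant-velocity Kalman filter that converts gyroscope rate signals
    into smoothed cursor trajectories. Seeded synthetic-scene generators
    provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
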