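Package: xfcacoh
Title: Within- and Cross-Frequency Cortico-Kinematic Canonical Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate estimation of coupling between multichannel
    electrophysiological recordings (EEG) and peripheral kinematic signals
    (accelerometry). Implements canonical coherence (caCOH), which finds real
    spatial filters maximizing coherence between two channel spaces at a
    frequency bin, and its cross-frequency extension (XF-caCOH), in which the
    slow peripheral signal is frequency-warped by an integer factor before
    coherence maximization. Includes n:m phase-synchronization indices,
    Hilbert-transform frequency warping, Welch cross-spectral estimation,
    spatial-pattern recovery metrics, a simulation framework with a synthetic
    leadfield and 1/f dipole background noise, and permutation-based
    significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
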