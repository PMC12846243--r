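Package: palmppg
Title: Palm-Video Remote Photoplethysmography Waveform Reconstruction
Version: 0.1.0
Authors@R: person("palmppg", "developers", role = c("aut", "cre"),
    email = "palmppg@example.org")
Description: Tools for reconstructing high-fidelity remote
    photoplethysmography (rPPG) waveforms from palm-region video.
    Implements coarse green-channel signal extraction over a region of
    interest, ensemble empirical mode decomposition (EEMD) baseline-drift
    removal, a conditional one-dimensional U-Net generative adversarial
    network with gated skip connections and peak-aware, time-domain and
    spectral losses, and a waveform-morphology evaluation pipeline
    (cycle segmentation, template averaging, fiducial indices and
    two-site comparison).  A synthetic paired palm-video/PPG generator
    makes the whole pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
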