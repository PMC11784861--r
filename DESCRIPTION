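Package: cortexwaves
Title: Traveling-Wave Detection, Ensemble Analysis, and Balanced-Network
    Simulation for Cortical Surface Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking cortical-surface traveling waves to
    translaminar circuit patterns. Implements generalized-phase estimation of
    the instantaneous phase of wideband grid LFP, single-trial traveling-wave
    detection via circular-linear phase-distance correlation against an
    electrode-shuffle null, wave kinematics (wavenumber, frequency, speed) and
    phase-gradient directionality, late-wave trial classification, a calcium
    ensemble pipeline (event binarization, activity-vector cosine similarity,
    eigenvalue significance testing, and Sorensen-Dice functional
    connectivity), laminar current source density with Vaknin padding and
    spectral profiling, whisker kinematics (Menger curvature, touch detection,
    d-prime), and a scaled-down conductance-based balanced-state spiking
    network with distance-dependent conduction delays. Every input the
    pipeline consumes can be generated synthetically with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
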