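Package: fretkin
Title: Simulation and Kinetic Inference for Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking kinetic inference from camera-based
    single-molecule FRET (smFRET) time traces. Simulates realistic intensity
    trajectories from a continuous-time Markov kinetic model with
    photobleaching-limited trace lengths, frame-integration (camera blurring),
    state-specific Gaussian channel noise, per-molecule intensity variation and
    dye blinking, while retaining the ground truth. Fits ensemble hidden Markov
    models with Gaussian emissions on the FRET efficiency across many traces,
    idealizes state paths by Viterbi decoding, extracts censoring-annotated
    dwell times, converts transition probabilities to rate constants, selects
    the number of states by BIC and attaches parametric-bootstrap confidence
    intervals. Evaluation utilities quantify the finite-data lower bound on
    rate-constant uncertainty, cumulative dwell-time distributions implied by a
    kinetic model, signal-to-noise ratio from FRET histograms, deviations from
    ground truth, coefficients of variation, and non-equilibrium cycle free
    energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    mclust,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
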