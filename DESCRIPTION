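Package: nanorotor
Title: Single-Molecule Nano-Rotor Twist Traces, Loop-Translocation Events
    and Ensemble Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ultrafast single-molecule DNA twist
    measurements made with a plasmonic DNA-origami nano-rotor, plus the
    ensemble kinetics that accompany them. Converts tracked gold-nanoparticle
    spot positions to unwrapped rotor angles, segments two-level
    (free/bound) angular traces with a Gaussian-emission hidden Markov
    model, detects and quantifies sawtooth DNA loop-translocation events
    (maximum loop size, ramp rate, pre/post state, clustering), fits
    dwell-time exponential mixtures and bimodal Gaussian mixtures by EM,
    computes stopped-flow fluorescence anisotropy, exponential phase fits,
    phosphate-release calibration and biphasic ATPase burst amplitudes,
    and detects sliding initiation events in confocal kymographs. A
    synthetic-data module generates every input with known ground truth
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    fitdistrplus,
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
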