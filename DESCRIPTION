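Package: nervechip
Title: Simulation and Analysis of Microchannel Nerve-on-a-Chip Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for peripheral-nerve electrophysiology in microchannel
    electrode arrays. Simulates extracellular single-fiber action potentials
    (SFAPs) propagating through a microchannel with position-dependent
    amplification, stimulation and onset artifacts, calibrated noise and
    repeated stimulation; reproduces the acquisition processing chain
    (zero-phase band-pass filtering, cubic-spline up-sampling, threshold spike
    detection and waveform metrology); implements the velocity-selective
    recording (VSR) delay-and-sum estimator on the integer-shift velocity grid
    with its success-rate statistic and discard rules; fits and interrogates a
    linear response-surface model of the success rate against channel geometry
    and waveform features; and quantifies opto-thermal neuroinhibition via a
    first-order thermal model, normalized signal density (NSD) with fast/slow
    fiber separation, exponential kinetics fits and factorial ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    car,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
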