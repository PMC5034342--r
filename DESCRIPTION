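Package: neurobypass
Title: Closed-Loop Neural Bypass Simulation with a Matsuoka CPG Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of an intracortical neural bypass for
    rhythmic movement restoration. Implements a two-neuron mutually
    inhibitive Matsuoka central-pattern-generator (CPG) oscillator with a
    genetic-algorithm parameter search, a synthetic multichannel neural
    recording generator with cue schedules and stimulation artifacts,
    stimulation-artifact excision and mean-wavelet-power (MWP) feature
    extraction (stationary db4 transform, scales 3-6), one-vs-rest SVM
    movement decoders with highest-score-above-zero arbitration, and a
    closed-loop virtual neuromuscular stimulation plant with a
    kinematics-based movement classifier and frame-level evaluation
    statistics (accuracy, sensitivity, specificity, permutation test,
    cue-correlation maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
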