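Package: mtlunitize
Title: Unitization Analysis of Single-Neuron and LFP Responses in the Human MTL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for follow-up sessions of human medial temporal
    lobe (MTL) recordings in which a small set of pictures is presented many
    times while sorted single-unit spike trains and local field potentials
    (LFP) are recorded. Implements instantaneous firing-rate estimation and a
    three-criterion response-detection rule, response strength and latency
    quantification, trial-label permutation tests for strength, latency and
    spike-waveform differences, cross-neuron surrogate-pair nulls, naive-Bayes
    leave-one-out decoding of stimulus identity from spike counts, theta-band
    evoked-power latency estimation, spike-LFP phase-locking analysis with
    trial-shuffle surrogates, web-hit based association scoring between
    stimuli, and population-level statistics relating response count, strength
    and latency. A seeded synthetic-session generator with known ground truth
    (Poisson spiking, 1/f plus theta-burst LFP, von Mises phase coupling,
    block-structured association scores) supports recovery and calibration
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
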