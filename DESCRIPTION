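Package: meaplast
Title: Optogenetic Connectivity Probing, Plasticity Metrics and Burst Replay
    Decoding for Multielectrode-Array Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for optogenetically stimulated cortical cultures
    recorded on multielectrode arrays (MEAs). Designs random-dot probing
    movies, tetanus trains and pattern-presentation schedules; infers directed
    stimulus-position to electrode connectivity from cross-correlation
    histograms (CCH) with a Poisson peak test and a trial-response criterion;
    quantifies synaptic-efficacy changes between probings (P/N/R summaries
    with capping), burstiness, synchronized network bursts (SNBs) and culture
    quality control; decodes burst "replay" of stimulus patterns with a
    support-vector classifier and computes a normalized familiarity metric.
    Ships a synthetic spiking-network simulator with tetanus- and
    random-dot-movie plasticity transforms so every stage can be exercised and
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'cch.R'
    'plasticity.R'
    'replay.R'
    'patterns.R'
    'network.R'
    'simulate.R'
    'schedules.R'
    'experiment.R'
    'io.R'
    'meaplast-package.R'
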