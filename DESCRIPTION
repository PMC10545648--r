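Package: vanlp
Title: Threshold-Tracked Awareness Analysis for Single-Trial ERP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for EEG studies of visual awareness at
    the detection and identification thresholds. Provides adaptive up-down
    staircases that track stimulus opacity, probit psychometric threshold fits,
    a synthetic generator for trial-level behaviour and multichannel ERP epochs
    (visual awareness negativity and late positivity components), at-threshold
    trial selection by a binomial chance criterion, window mean-amplitude
    extraction with deterministic artifact flagging, trial-level robust Bayesian
    hierarchical regression (Student-t likelihood, blocked Gibbs sampler) with
    Savage-Dickey Bayes factors, probability of direction and ROPE indices, and
    a 16-setting multiverse robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    coda,
    jsonlite,
    rjags
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
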