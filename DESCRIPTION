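Package: qeegpipe
Title: Quantitative EEG Power, Lagged Coherence and Global Functional
    Connectivity Pipeline for Rodent Pharmaco-EEG
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for drug-induced broadband desynchronization
    and disconnection in freely moving rodent EEG. Covers artifact-free
    behavioral-inactivity segment selection, Welch spectral power per 1-Hz
    bin and canonical band, phase-lagged coherence and a per-subject global
    functional connectivity (GFC) statistic, Box-Cox (lambda = 0)
    baseline normalization, mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction and Bonferroni post-hocs, thin-plate
    spline topographic maps with pointwise significance, and a synthetic
    multichannel EEG generator with analytically known band powers and
    lagged coherences for parameter-recovery validation. Recordings are
    stored as EDF with YAML sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
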