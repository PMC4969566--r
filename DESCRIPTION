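Package: iekappa
Title: Information-Equilibrium Analysis of EEG Voltage Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-instant information-transfer constants (kappa)
    from single-channel voltage time series at multiple time scales,
    following the information-equilibrium treatment of EEG: kappa is the
    ratio of the log absolute voltage increment to the log time interval.
    Segments are summarized by the mean kappa and the fraction of
    low-information-transfer instants; periodicity in the kernel-density
    estimate of a segment's kappa values is quantified by
    significance-thresholded normalized Lomb-Scargle power; and states of
    consciousness are compared with repeated-measures ANOVA and Bonferroni
    correction. Includes EDF/EDF+ and CSV readers, a synthetic-signal
    generator (ramps, fractional Brownian motion by circulant embedding,
    power-law-increment signals, multi-subject cohorts) with analytic
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
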