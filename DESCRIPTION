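Package: ewsmotion
Title: Early Warning Signals of Intentional Motion Onset
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of early warning signals (EWS) that
    precede the onset of intentional motion. Provides a stochastic saddle-node
    (fold) bifurcation simulator with matched step-function controls, a
    synthetic multi-sensor motion-capture generator for Attacker/Blocker
    reaching trials, sliding-window EWS statistics (lag-1 autocorrelation,
    autocorrelation decay time, variance) with threshold-based rise detectors,
    power-law fitting of the variance divergence near the critical point,
    density-filtered regression of motion-onset times on EWS times, and
    reaction-time distribution comparisons (rank-sum, Kolmogorov-Smirnov,
    decile shift function).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
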