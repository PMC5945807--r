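Package: stopsignal
Title: Stop-Signal Task Simulation, Bayesian Stop-Expectation, and
    Directed Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing proactive control in the stop-signal
    task. Simulates race-model subjects under a staircase-titrated stop
    signal delay, computes trial-wise Bayesian estimates of stop-signal
    probability P(Stop), estimates the stop-signal reaction time (SSRT)
    from mid-run critical delays, quantifies sequential and fore-period
    effects, fits ROI-level event-related general linear models with
    serially orthogonalised parametric modulators, and tests directed
    influence between ROI time series with multivariate Granger
    causality against phase-randomised surrogate nulls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
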