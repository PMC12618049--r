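Package: saccmix
Title: Two-Process Decomposition of Early Saccades in Foreperiod Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulation and analysis of anticipatory eye movements in
    blocked foreperiod paradigms. Generates synthetic gaze recordings with
    a two-process early-saccade structure (impulsive responses with
    foreperiod-independent latency and anticipatory responses obeying
    scalar expectancy), detects saccades from raw traces with
    amplitude/velocity/acceleration criteria, classifies them into early
    and visually guided categories, decomposes early-saccade latency
    distributions with a from-scratch Gaussian-mixture EM and an analytic
    between-component crossing point, and recovers latency, variability
    and incidence-rate trends with two-stage and random-intercept
    estimators, including Shannon-surprise quantification of spatial
    uncertainty.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
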