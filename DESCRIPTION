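Package: trialvar
Title: Intraindividual Variability of Single-Trial ERP Amplitudes via
    Bayesian Location-Scale Multilevel Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying trial-to-trial (within-person) variability of
    event-related potential (ERP) amplitudes. Simulates trial-level ERP score
    tables and toy epoched waveforms with person-specific means and residual
    variances; scores epochs by baseline adjustment and time-window mean
    amplitude with collapsed-localizer window selection; fits Bayesian
    mixed-effects location-scale models (MELSM) with fixed and correlated
    random effects on both the mean and the log residual standard deviation
    via an adaptive Markov chain Monte Carlo sampler; compares location-scale
    against location-only fits with Pareto-smoothed importance-sampling
    leave-one-out cross-validation; applies credible-interval decision rules
    for group differences in variability; and characterizes data quality via
    generalizability-theory dependability and standardized measurement error.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
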