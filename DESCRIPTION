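Package: eprr
Title: Exposure Potential, Restriction, and Bias Amplification in
    Risk-Ratio Regression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and exact (population-level) tools for studying
    whether to restrict an analysis to individuals with exposure
    potential, i.e. those who could possibly be exposed. Builds
    multiplicative-risk data-generating mechanisms in which one stratum
    (men) has zero probability of exposure, samples reproducible binary
    cohorts, fits log-binomial (risk-ratio) regressions under the six
    canonical analysis plans (crude, adjusted for a confounder and/or
    sex, restricted to women), and summarizes Monte Carlo bias, empirical
    standard error and mean squared error against the true conditional
    risk ratio. An exact 16-cell joint-distribution oracle provides
    g-formula counterfactual risks and each estimator's asymptotic limit,
    and diagnostics cover the unexposed-mean decomposition, the partial
    exchangeability check with its collider caveat, positivity reports,
    and the four-scenario taxonomy of how restriction on the
    exposure-potential indicator affects bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
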