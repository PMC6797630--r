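Package: ddspill
Title: Delay Discounting Across Commodities: Adaptive Measurement and
    Spillover Hypothesis Comparison
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how a motivational state (such as hunger)
    changes delay discounting of in-domain and out-of-domain commodities.
    Implements hyperbolic and related discount functions, a
    lapse-contaminated probit model of binary inter-temporal choice,
    per-session Bayesian posterior estimation of log discount rates via
    MCMC, an information-gain adaptive trial-design chooser emulating a
    fixed-delayed-reward protocol, a Cauchy-likelihood maximum-likelihood
    comparison of six candidate models of condition-induced change in log
    discount rate (with AIC/BIC and model weights), and a synthetic-study
    generator so the full pipeline can be exercised without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
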