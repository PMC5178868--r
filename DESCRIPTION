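Package: metaconf
Title: Bayesian Models of Decision Confidence and Metacognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of decision confidence under first-order,
    postdecisional and second-order Bayesian observer models. Internal evidence
    for choices and confidence is modelled as correlated draws from a bivariate
    Gaussian; confidence is the posterior probability that the chosen action
    matched the world state, computed under the observer's (possibly
    miscalibrated) beliefs about the generative parameters. Includes a trial
    simulator, closed-form confidence posteriors with a Monte-Carlo oracle,
    metacognition metrics (type 2 ROC, maximum-likelihood meta-d', calibration
    curves, error-detection rate), and config-driven simulation experiments
    covering the X-pattern, error detection, action effects on confidence,
    hyper-/hypo-metacognitive sensitivity and hyperparameter-driven
    miscalibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
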