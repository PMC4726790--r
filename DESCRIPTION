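Package: relbelief
Title: Relative Belief Inference: Evidence, Strength, Bias, and
    Prior-Data Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures statistical evidence by the relative belief ratio,
    the factor by which data change the prior into the posterior at a
    hypothesized parameter value.  Provides evidence assessment with a
    calibrated strength, least-relative-surprise estimation with
    evidence-ordered credible regions, exact closed-form backends for the
    Bernoulli-beta and normal (known variance) conjugate families, a
    generic discretized engine with a Monte Carlo path for marginal
    parameters, pre-experimental measurement of the bias a prior induces
    for or against a hypothesis together with sample-size design to
    control it, a prior-data conflict check based on the prior predictive
    distribution of the minimal sufficient statistic, and the closed-form
    two-state (trait/class) example that illustrates protection against
    the prosecutor's fallacy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
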