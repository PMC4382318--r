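Package: crtpowersim
Title: Simulation-Based Power Analysis for Cluster-Randomized Trials with
    Variable Cluster Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo power estimation for equal-armed, continuous-outcome
    cluster-randomized trials (CRTs). Calibrates the treatment effect size so
    that a trial with a given number of equal-sized clusters has nominal 80%
    power, simulates hierarchical normal outcomes under fixed or
    negative-binomial-distributed cluster sizes at a chosen coefficient of
    variation, tests each simulated trial with a random-intercept linear mixed
    model, traces power curves over the number of clusters, and interpolates
    the number of clusters required to reach a target power. Quantifies how
    cluster-size variability inflates the required number of clusters relative
    to the fixed-size formula value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
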