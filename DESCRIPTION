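Package: bsadose
Title: Bayesian Stochastic Approximation Design for Phase I Dose-Finding
    Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequential dose-finding for phase I clinical trials by Bayesian
    stochastic approximation. The dose-toxicity curve is modelled locally by a
    line segment on the subinterval containing the current dose, a
    noninformative order prior is placed on the toxicity rates at the
    subinterval endpoints, and the posterior mean of the target quantile
    drives a no-skipping neighborhood transition rule. Includes frequentist
    quick actions (pre-toxicity fast escalation, Wald-type logit interval
    moves, toxicity termination), borrowing of historical information through
    prior effective sample size pseudo-observations, pre-printable decision
    trees, and a trial simulator with standard operating-characteristic
    metrics (correct-selection rate, allocation to and above the maximum
    tolerated dose, expected toxicity count).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
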