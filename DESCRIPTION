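Package: manychoice
Title: Gaze-Dependent Choice Models for Many-Alternative Forced Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Likelihood-based modelling of choices and response times in
    many-alternative value-based decisions with eye tracking. Implements
    three gaze-dependent decision models -- a probabilistic satisficing
    model, an independent evidence-accumulation race, and a relative
    (gaze-weighted linear) accumulator -- each in a passive-gaze and an
    active-gaze variant with multiplicative and additive gaze biases.
    Provides gaze-stream cleaning and trial exclusion rules, behavioural
    summary measures including a regression-based gaze-influence
    statistic, per-subject Metropolis sampling under box-uniform priors
    with WAIC model comparison, forward trial simulators with a uniform
    contaminant mixture, and a synthetic-experiment generator for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
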