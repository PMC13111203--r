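Package: perchtask
Title: Simulation and Analysis of a Cued Postural Perturbation Task for Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a closed-loop operant paradigm in
    which head-free mice stand bipedally on a perch, lick a spout for water,
    and experience backward platform translations that are either unpredictable
    or preceded by a 1-s auditory cue. Provides a deterministic-given-seed
    event-driven simulator of the task state machine (trial scheduling,
    truncated-exponential perturbation delays, trapezoidal platform velocity
    profiles), a stochastic virtual mouse that emits lick trains and synthetic
    pose-tracking output, the kinematic quantification pipeline (nose-to-spout
    distance, capping, baseline subtraction, exclusion rules, windowed maxima),
    trial-outcome classification with binomial confidence intervals, and
    per-animal linear and logistic mixed-effects models with random session
    intercepts, including simulation-based parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
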