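Package: replibelief
Title: Belief Updating and Strategy Classification for Sets of
    Replication Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how researchers interpret the results of a
    set of replication experiments that all test the same theory.  Implements
    the normative Bayesian posterior belief in a theory given k significant
    results out of N experiments, three vote-counting/averaging heuristics
    (deterministic vote counting, proportional vote counting, and averaging
    prior belief with significance), and a Bayesian procedure that classifies
    each participant's response pattern into one of these strategies using
    truncated-normal response likelihoods, RMSE-based model fit, and a
    participant-specific benchmark gate.  Includes a synthetic-cohort
    generator that emulates the eight-scenario vignette design with known
    ground-truth strategies, decision noise, irregular responders and missing
    responses, plus pipeline functions for simulation, classification,
    reporting and strategy-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
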