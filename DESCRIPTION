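Package: recmstate
Title: Recurrent-Event Multistate Analysis for Hospitalization-Death Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analyzing recurrent hospitalizations with a terminal
    death event as a multistate process. Implements the illness-death model
    with recovery and its progressive (event-count indexed) expansion:
    counting-process data handling, nested competing-risks simulation of
    Markov and non-Markov (frailty or entry-time driven) scenarios under
    random or state-dependent censoring, nonparametric estimators
    (Nelson-Aalen transition hazards and partly conditional rates,
    Kaplan-Meier, Aalen-Johansen state occupation, marginal mean number of
    events, average length of stay, between-arm event-per-time-alive ratios,
    basic bootstrap intervals), from-scratch semiparametric engines
    (Andersen-Gill, Prentice-Williams-Peterson, Ghosh-Lin proportional
    rates with inverse probability of censoring weights) with model-based
    and robust cluster variances, and a simulation pipeline for assessing
    Wald-type diagnostics of the Markov assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix,
    withr
Config/testthat/edition: 3
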