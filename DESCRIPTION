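Package: herdhmm
Title: Hidden Markov Behaviour Models for GPS-Tracked Cattle Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for GPS-collar surveys of Sahelian
    agropastoral cattle herds. Reads and cleans time-stamped collar
    tables, segments them into regular 30-minute sequences, extracts
    step lengths and turning angles, and fits N-state hidden Markov
    behaviour models with zero-inflated positive step laws and von
    Mises turning-angle emissions, optionally with covariate-dependent
    transition probabilities. Model fitting uses multistart nonlinear
    likelihood minimisation; state counts are compared by BIC and
    decoded by the Viterbi algorithm. Decoded fixes are annotated with
    land-use units by point-in-polygon joins and summarised into
    activity budgets, daily movement metrics and transhumance phase
    records. A synthetic survey generator with known ground truth makes
    every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    yaml,
    mgcv,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
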