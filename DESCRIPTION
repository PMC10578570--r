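Package: mcqimpute
Title: Scoring and Missing-Response Imputation for the Monetary Choice
    Questionnaire
Version: 0.1.0
Authors@R:
    person("Alex", "Morgan", email = "alex.morgan.mcq@posteo.net",
           role = c("aut", "cre"))
Description: Scores the 21- and 27-item Monetary Choice Questionnaire (MCQ),
    a binary-choice instrument for the hyperbolic delay-discounting rate k,
    via the consistency-score switch-point procedure (overall, small, medium,
    large, and composite k estimates plus the proportion-of-delayed-choices
    score). Implements four approaches for handling missing responses that
    exploit the questionnaire's three-amount-set structure: per-item mode
    imputation, the group geometric mean (GGM) relaxation of the composite k,
    and item-nearest-neighbour (INN) imputation with or without random
    backfill. Ships a synthetic-respondent generator (heterogeneous
    log-discount rates, logistic choice noise, correlated covariate) and a
    Monte Carlo harness that evaluates each approach under uniform removal of
    a fixed number of responses per respondent, reporting mean difference,
    root-mean-square deviation, correlation with the true composite k,
    unimputable-respondent counts (with their analytic expectation), and the
    change in correlation with an external covariate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
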