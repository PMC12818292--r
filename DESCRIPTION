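Package: olfdyad
Title: Dyadic Olfactory Decision-Making: Simulation, Scoring and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying collective benefit in dyadic olfactory
    forced-choice tasks. Implements clinical-style scoring of threshold,
    discrimination and identification subtests (including the adaptive
    2-down/1-up threshold staircase as a state machine), ability-similarity
    and collective-benefit statistics, conflict classification and
    resolution summaries, quartile-based dyad matching, signal-detection
    observer models with confidence and three dyadic aggregation rules
    (voting, confidence-deferral, evidence pooling), a synthetic study
    generator with transcript-derived word and confidence-lexicon metrics,
    and the downstream inference stage: clustered logistic and Poisson
    mixed models, paired tests, OLS regressions and BIC-based Bayes-factor
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    glmnet,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
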