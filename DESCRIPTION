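Package: rpsftcr
Title: Rank-Preserving Structural Failure Time Models for Treatment
    Switching with Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cause-specific treatment effects in randomized
    trials where control-arm patients switch to the experimental
    treatment at disease progression and more than one failure type is
    possible.  Extends the rank-preserving structural failure time
    (RPSFT) model to two competing causes via a two-dimensional
    G-estimation grid search on cause-specific hazards, with
    re-censoring of counterfactual times.  Includes a cause-specific
    hazards trial simulator (exponential failure times, staggered
    uniform entry, administrative censoring, progression-triggered
    switching), naive comparators (intention-to-treat and
    censor-at-switch, on cause-specific and composite endpoints),
    Monte Carlo performance summaries, and scenario orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
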