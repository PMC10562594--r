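Package: recalldyn
Title: Organization Analyses for Free-Recall Experiments
Version: 0.1.0
Authors@R:
    person("Dev", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dynamics of verbal free recall:
    lag conditional-response probability (lag-CRP) curves, percentile-rank
    temporal and semantic clustering factor scores, serial-position and
    probability-of-first-recall curves, and intrusion scoring. Includes a
    constrained study-list generator that places high-similarity word pairs
    at non-adjacent serial positions, a synthetic recall-process simulator
    based on a mixture of temporal-contiguity and semantic-similarity
    retrieval cues, and the mixed-design statistics (one-sample and Welch
    t tests, 2x2 split-plot ANOVA, sign-flipping permutation tests) used
    to contrast within-subject context conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
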