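Package: coda24
Title: Compositional Analysis of 24-Hour Time-Use Behaviours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compositional data analysis pipeline for children's 24-hour
    time-use behaviours measured as activity-intensity (sedentary, light,
    moderate-to-vigorous activity, sleep) and activity-type (sitting,
    standing, walking, running, lying) compositions. Provides Aitchison
    geometry primitives (closure, isometric log-ratio transforms,
    compositional means, variation arrays), log-ratio
    expectation-maximisation imputation of rounded zeros and missing parts,
    compositional MANOVA with Pillai's trace and partial eta squared,
    pairwise Hotelling post-hoc tests with Holm adjustment, bootstrapped
    per-part log-ratio contrasts with percentage back-transformation,
    24-hour Movement Guidelines adherence classification with contingency
    tests and Cramer's V, a logistic-normal synthetic cohort generator, and
    reporting helpers (geometric-mean bar plots, ternary plots, a
    command-line driver).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
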