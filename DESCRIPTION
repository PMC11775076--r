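Package: ccaf
Title: Analysis of Concurrent-Choice Alcohol-Food Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for two-alternative concurrent
    choice experiments in which participants choose between an alcohol and a
    snack reward whose point values vary trial by trial. Generates
    counterbalanced trial schedules, simulates cohorts of subjects with
    logistic choice behaviour, fits binomial psychometric functions
    parameterised by the point of subjective equality (PSE) and slope,
    computes parametric-bootstrap confidence intervals, classifies individual
    reward preference from the PSE interval, and runs the group-level
    statistics (chi-squared contingency tests and a split-plot ANOVA on
    empirical-logit transformed choice percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    withr
Config/testthat/edition: 3
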