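Package: normrange
Title: Portion-Size Norm Ranges, Intended Consumption, and Categorical
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice portion-size
    normality judgments, 7-point intended-consumption ratings, and paired
    relative-size discrimination trials. Estimates collective and individual
    "norm ranges" (the span of portion sizes a clear majority judges normal),
    classifies portions and portion pairs against those ranges, and runs the
    category-wise intention, boundary-sensitivity, and discrimination
    analyses (repeated-measures ANOVA with Greenhouse-Geisser correction and
    partial eta-squared, Bonferroni-corrected follow-ups, reaction-time
    trimming, and a Weber-versus-categorical decomposition of discrimination
    accuracy). Includes a synthetic-cohort generator implementing the
    hypothesised generative structure (two-boundary categorical perception,
    piecewise-linear intention, Weber-law discrimination with an optional
    categorical boost) so every pipeline stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
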