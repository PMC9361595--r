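Package: diagbias
Title: Diagnostic Test Characteristics of Biased and Ignorant Testers
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative modelling of how cognitive bias and ignorance
    degrade the performance of a human diagnostician.  A diagnostic test
    (or a dichotomous human judgement) is represented as a column-stochastic
    2x2 sensitivity-specificity matrix; sequential testers compose by matrix
    multiplication; a tester's bias or ignorance is itself such a matrix
    that multiplies onto the primary test.  Positive predictive values are
    obtained from Bayes' formula and iterated over chains of consecutive
    test results, including the search for the minimum number of positive
    results needed to exceed a posterior threshold.  Includes generators
    for the canonical worked-example tables and curve families, a JSON
    scenario-file reader, CSV writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
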