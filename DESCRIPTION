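Package: oradjust
Title: Adjusting Odds Ratios for Differential Exposure Misclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative bias analysis for recall bias (differential exposure
    misclassification) in case-control studies. Elicits conjugate Beta priors
    for sensitivity and specificity from a validation cross-tabulation of
    self-reported versus gold-standard exposure, performs fixed-value matrix
    correction of an observed 2x2 table with Woolf confidence intervals on the
    non-integer corrected counts, runs summary-level probabilistic bias
    analysis with correlated Beta draws and conventional random error, and
    fits a Bayesian misclassification model (binomial likelihood on apparent
    exposure counts, Beta priors on sensitivity and specificity, uniform prior
    on control prevalence, null-centred vague prior on the log odds ratio) by
    blocked adaptive random-walk Metropolis with split-Rhat and effective
    sample size diagnostics. Includes a synthetic case-control generator with
    known truth so every adjustment stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
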