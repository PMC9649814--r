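Package: numsense
Type: Package
Title: Numerosity Psychophysics and Default Bayesian Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for visual numerosity-categorization experiments and their
    group-level Bayesian analysis. Builds geometric stimulus ladders, anchored
    trial schedules and non-overlapping dot-field layouts; simulates observers
    obeying Weber's law and whole two-group study cohorts; fits cumulative
    Gaussian psychometric functions by maximum likelihood and derives the point
    of subjective equality, just-noticeable difference and Weber fraction;
    converts raw math-battery scores to age-normative z-scores with explicit
    missing-data handling; computes default log10 Bayes factors (JZS two-sample
    t-test, rank-based two-sample test, Kendall and Pearson correlations,
    ANCOVA inclusion, contingency tables) plus noncentral-t power analysis; and
    orchestrates the full study pipeline behind a command-line interface with
    CSV and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
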