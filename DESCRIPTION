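Package: pleioq
Title: Heterogeneity-Based Detection of Horizontal Pleiotropy in
    Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting horizontal pleiotropy in two-sample
    summary-data Mendelian randomization with the classical heterogeneity
    statistics. Implements the inverse-variance-weighted (IVW) causal
    estimate with Cochran's Q and its per-variant decomposition, MR-Egger
    regression with Rucker's Q' and its per-variant decomposition,
    chi-squared outlier flagging at uncorrected and Bonferroni familywise
    thresholds, outlier removal with refitting, a seeded simulator for
    balanced and directional pleiotropy under the InSIDE assumption
    (including a weak-instrument mode that violates the no-measurement-error
    assumption), and Monte-Carlo drivers for power, type-I-error and
    per-variant contribution-profile studies. A command-line front end
    exposes analysis, simulation and power studies as shell subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
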