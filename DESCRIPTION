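Package: eegtrp
Title: Task-Related EEG Band Power Analysis with Nonparametric Factorial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for task-related power (TRP) analysis of
    multichannel EEG recorded during design tasks: DC-offset removal, 4-45 Hz
    FIR band-pass filtering, muscle-artifact removal by blind source separation
    based on canonical correlation analysis (BSS-CCA), event-driven epoch
    segmentation, sliding-window amplitude artifact rejection, theta/alpha/beta
    band-power and log-ratio TRP computation, and nonparametric factorial
    statistics (aligned rank transform repeated-measures ANOVA with partial eta
    squared, Wilcoxon signed-rank post hocs with Bonferroni correction and
    effect sizes). Includes a synthetic-EEG cohort simulator with controlled
    band-power structure and injectable artifacts for validation against known
    ground truth, and EDF/CSV I/O for recordings and event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
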