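Package: dvheval
Title: Dosimetric and Radiobiological Evaluation of Radiotherapy Plans from
    Dose-Volume Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates external-beam radiotherapy plans from cumulative
    dose-volume histograms (DVHs): coverage indices (D2 through D98),
    ICRU 83/91 homogeneity and gradient indices, generalized equivalent
    uniform dose (gEUD), linear-quadratic cell-survival EUD, and EQD2
    isoeffect conversions. Includes the paired-cohort statistical battery
    used in plan-comparison studies (Shapiro-Wilk normality with a
    small-sample critical-value table, exact tie-aware Wilcoxon signed-rank
    testing, normal-approximation confidence intervals), Monte Carlo
    resampling of index distributions from cohort summaries, and a
    calibrated synthetic paired-cohort generator for single-fraction
    heterotopic-ossification prophylaxis planning studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
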