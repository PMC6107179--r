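Package: enerbal
Title: Energy Expenditure, Accelerometry and Energy-Balance Analysis for
    Exercise Training Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the energy-balance analysis of supervised exercise
    interventions in three-arm (control / training / training-detraining)
    repeated-measures designs: resting metabolic rate from indirect
    calorimetry via the Weir equation, decomposition of exercise-session
    energy expenditure into aerobic, blood-lactate-derived anaerobic and
    excess post-exercise oxygen consumption components, MET-hour training
    load, accelerometer count-stream processing (vector-magnitude non-wear
    detection, intensity cut-points, wear-time validation, activity
    kilocalories), seven-day diet-recall summaries with isocaloric
    prescription checks, a daily/weekly/period energy ledger with fat-mass
    equivalents, mixed repeated-measures ANOVA with Mauchly's test and
    Greenhouse-Geisser correction, Bonferroni post-hoc tests, bias-corrected
    Hedges' g effect sizes, ANCOVA adjustment, and a fully deterministic
    synthetic trial generator with a known ground truth for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
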