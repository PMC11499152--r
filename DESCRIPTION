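Package: gazedpa
Title: Divergence Point Analysis for Blank-Screen Visual-World Eye-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the timecourse analysis of anticipatory fixations in
    blank-screen visual-world experiments: mapping raw gaze samples to
    remembered picture areas of interest, binning looks to the factual versus
    the illusory referent into 200 ms bins, per-bin weighted empirical-logit
    regression, bootstrap divergence-point estimation with percentile
    confidence intervals, and difference distributions between conditions and
    between languages. Includes a synthetic-data generator with known
    ground-truth divergence onsets for validation, window-level descriptive
    statistics, mixed-effects fixation-duration models, proficiency
    correlations, and a paired-means sample-size computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
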