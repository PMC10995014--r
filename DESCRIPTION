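Package: cosinorHRV
Title: Diurnal Cosinor Rhythmometry of Ambulatory Heart Rate and Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying diurnal (24-h) rhythms of heart rate and vagally
    mediated heart rate variability (RMSSD) from ambulatory beat-to-beat interval
    recordings. Provides reading/writing of plain-text inter-beat-interval (IBI)
    files, quality control (plausibility filtering, automated ectopic-beat
    correction, smoothness-priors detrending, clock-aligned 5-minute segmentation),
    per-segment mean heart rate and RMSSD, single-subject least-squares cosinor
    fits with zero-amplitude rhythm-detection tests, population-mean cosinor
    summaries with Bingham-type confidence intervals, two-group differential
    rhythmicity analysis (MESOR, amplitude, acrophase) with Hedges' g effect sizes
    and circular acrophase-shift conversion to clock hours, a covariate-adjusted
    correlation/regression layer, and a seeded synthetic cohort generator with
    known ground-truth rhythm parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
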