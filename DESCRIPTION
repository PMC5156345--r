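Package: sesforage
Title: Dive Segmentation, Prey-Encounter Detection and Foraging Models for
    Daily-Diary Bio-Logging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-resolution bio-logging records from
    deep-diving marine predators (1 Hz depth, 16 Hz tri-axial acceleration and
    magnetometry, intermittent surface GPS fixes). Detects prey-encounter
    events from high-frequency acceleration by per-axis two-state clustering
    with a tri-axial coincidence rule, derives body posture (pitch, roll,
    tilt-compensated heading) and swimming effort, corrects pressure-sensor
    drift, delimits dives and their descent/bottom/ascent phases from wiggle
    and step events, assembles a per-dive covariate table, and fits the
    associated statistical models: negative-binomial count models with an
    exposure offset, linear mixed models with Nakagawa marginal/conditional
    R-squared, and variable-dispersion beta regression, with backward-AIC and
    polynomial-degree model selection. Includes a synthetic daily-diary
    simulator with ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    lme4,
    glmmTMB,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
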