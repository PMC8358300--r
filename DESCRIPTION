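Package: posturo
Title: Stabilometric Analysis of Center-of-Pressure Sway for Sensory
    Organization Balance Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative posturography with a six-condition
    sensory-organization protocol. Derives center-of-pressure (COP)
    trajectories from force-plate force/moment channels, segments
    recordings into trial windows, and computes the standard
    stabilometric measure battery (directional mean distance, mean
    velocity, 95% confidence ellipse sway area, and directional mean
    sway frequency). Provides the nonparametric repeated-measures
    statistics used in balance studies (Friedman omnibus, a-priori
    Wilcoxon signed-rank contrasts with Rosenthal effect sizes),
    scoring for the Simulator Sickness Questionnaire, igroup Presence
    Questionnaire, and System Usability Scale, and a seeded synthetic
    sway-cohort generator calibrated to published condition-level
    measure distributions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
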