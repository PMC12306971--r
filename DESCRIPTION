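Package: shadowtrial
Title: Trial-Based Analysis of Shadow-Evoked Escape Responses in Walking Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for single-animal, trial-based threat-response
    assays in which walking flies are presented with repeated passing-shadow
    stimuli inside linear tunnels. Converts centroid tracking tables and a
    stimulus schedule into stimulus-aligned speed and acceleration traces,
    classifies each trial as stop, slow down, speed up or no reaction using
    speed and acceleration thresholds, measures stop durations, builds
    speed-conditioned response-probability curves, simulates speed-matched
    virtual-fly cohorts as a Monte-Carlo null model, and provides the group
    statistics used for genotype and age comparisons (Mann-Whitney tests,
    permutation dispersion tests, two-way ANOVA age trends). Includes a
    synthetic trajectory generator with planted, speed-dependent responses
    and full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
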