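Package: actiadhere
Title: Accelerometry-Based Adherence Scoring for Staged Pediatric
    Concussion Return-to-Activity Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores objective adherence to staged Return-to-Activity (RTA)
    protocols after pediatric concussion from waist-worn accelerometer
    epoch counts: non-wear detection and valid-day screening, cut-point
    intensity classification, activity-bout detection, machine-readable
    stage rules for RTA stages 1-3, and self-reported adherence labels
    derived from 48-hour symptom surveys.  Provides chance-corrected
    agreement (Cohen's kappa) and exact or normal-approximation
    Mann-Whitney U comparisons between objective and subjective
    adherence, a ground-truth synthetic cohort generator, and an
    end-to-end pipeline that writes study-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
RoxygenNote: 7.3.3
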