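Package: earnorms
Title: Normative Standardization and Scoring for the Emotion Authenticity
    Recognition Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Equivalent Scores (ES) normative pipeline for the
    Emotion Authenticity Recognition (EAR) test: deterministic scoring of the
    60-item two-judgment protocol into the ER and EA accuracy indices,
    regression-based demographic adjustment with transformed-predictor
    selection, non-parametric outer/inner tolerance limits on adjusted scores,
    5-level Equivalent Score banding, and clinical scoring against the
    published Italian adult norms.  A moment-calibrated synthetic cohort
    generator reproduces the normative sample's demographic stratification and
    score-covariate structure so that every stage of the pipeline can be
    exercised and validated without access to the original participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
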