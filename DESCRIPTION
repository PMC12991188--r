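Package: eyetriage
Title: Symptom-Based Ophthalmic Triage Support and Diagnostic-Accuracy
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rule-based triage support engine for recent-onset eye and
    vision symptoms, together with the biostatistical machinery used to
    evaluate such tools in practice. A conditional-logic multiple-choice
    questionnaire (defined declaratively in YAML) collects symptomatology,
    a symptom acuity table adapted from emergency eye-care triage guidance
    rates the asserted symptoms, and the maximal acuity drives an automated
    disposition to a service (emergency department or emergency eye clinic,
    community urgent eyecare, community optometry, pharmacist) and urgency
    band, with an immediate fast-path for chemical, blunt or high-velocity
    trauma. Masked symptom reports, study record tables, paired
    sensitivity/specificity with continuity-corrected McNemar tests, Cohen
    kappa with confidence intervals and a-priori interpretation bands,
    Mann-Whitney U, odds ratios, and a seeded synthetic vignette-cohort
    simulator support end-to-end desk-scale evaluation of triage accuracy.
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
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
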