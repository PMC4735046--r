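Package: critopt
Title: Optimal Diagnostic Criterion Sets from Chronicity and Comorbidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exhaustive search over diagnostic criterion subsets and
    endorsement thresholds for two-wave binary symptom panels. Every
    candidate rule (criterion subset plus count threshold) is scored on
    diagnostic persistence across waves and on Jaccard-based comorbidity
    with Axis I symptom disorders and Axis II personality-disorder
    clusters, combined through rank-based inverse-normal composites over
    a grid of persistence/comorbidity weights. Final rules are selected
    by min-max k-fold cross-validation and by consensus voting over
    per-fold optima, and competing diagnoses are compared on external
    validators with survey-weighted planned contrasts. Includes a
    synthetic two-wave panel generator with planted latent-severity
    structure for end-to-end testing without restricted survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
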