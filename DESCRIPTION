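Package: akicohort
Title: KDIGO Kidney Disease Classification and Cohort Analysis for
    Infection-Associated AKI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of acute kidney injury (AKI), acute kidney
    disease (AKD) and chronic kidney disease (CKD) in prospective
    infection cohorts where no documented baseline creatinine exists.
    Implements serum-creatinine based GFR estimating equations (4-variable
    MDRD, CKD-EPI 2009, full age spectrum, Cockcroft-Gault) together with
    their inversions, so that baseline creatinine can be back-calculated
    from an assumed GFR; KDIGO staging, incident AKI, recovery, AKD and
    CKD rules at admission, 48 hours and 3 months; qSOFA illness-severity
    scoring; a synthetic cohort generator with stored ground truth for
    validating every downstream stage; and the cohort statistical layer:
    group comparisons, logistic regression with a natural cubic spline
    age term and bootstrap percentile odds-ratio curves, Cox proportional
    hazards and Kaplan-Meier survival, and a minimal-detectable-odds-ratio
    power solver based on exact power of Fisher's test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    splines,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
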