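Package: pnucohort
Title: Prevalent New-User Cohort Designs with Time-Conditional Propensity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the prevalent new-user (PNU) cohort design for
    pharmacoepidemiologic studies comparing a newly introduced study drug
    with an established comparator: base-cohort assembly with washout,
    continuous treatment episodes, prescription-based, time-based and hybrid
    exposure-set construction, time-conditional propensity-score estimation
    by weighted exposure-set-conditional logistic regression with within-set
    sampling, positivity screening, chronological 1:1 nearest-score matching
    without replacement, as-treated follow-up, Cox effect estimation with
    robust standard errors, and covariate balance diagnostics. A synthetic
    electronic-health-record generator with known ground truth makes every
    stage testable without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
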