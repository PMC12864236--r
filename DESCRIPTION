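Package: pmindex
Title: Severity-Weighted Postoperative Complication Burden with the
    Accordion Grading System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the postoperative morbidity index (PMI), a
    severity-weighted complication burden per treated patient on a 0-1
    scale, from aggregate complication tables graded on the six-point
    Accordion severity scale. Provides inclusion-exclusion bounds on the
    proportion of patients with at least one complication, Monte Carlo
    uncertainty propagation (binomial event counts, triangular
    grade-weight uncertainty) with equal-tailed credible intervals and
    between-arm comparison summaries, intraclass-correlation reliability
    assessment of multi-rater complication grading, and a patient-level
    synthetic two-arm trial generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
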