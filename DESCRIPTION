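Package: biasaudit
Title: Reporting-Bias Audits of Meta-Analytic Literatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits a corpus of meta-analyses for reporting bias. Each
    meta-analysis is re-pooled with an inverse-variance random-effects model
    (DerSimonian-Laird) and screened with two reporting-bias statistics: the
    Egger regression asymmetry (small-study effect) test and the excess
    significance test, which compares the observed number of nominally
    significant primary studies against the number expected from per-study
    power under a plausible effect. Includes eligibility and sensitivity
    filters (minimum study counts, exclusion of small studies by death
    counts), per-research-area tabulations, ROBIS risk-of-bias judgment
    tallies for systematic reviews, and a synthetic-corpus generator with a
    selective-publication mechanism for estimating the tests' operating
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
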