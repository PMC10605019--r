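Package: ppsn
Title: Prognosis Predictive Score around Neoadjuvant Chemotherapy for
    Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives Youden-optimal cutoffs for peripheral-blood markers
    measured before and after neoadjuvant chemotherapy in advanced
    epithelial ovarian cancer, builds the 0-7 PPSN composite score from
    the seven dichotomized markers, and evaluates it against mortality
    and progression with diagnostic metrics, odds ratios with Wald
    intervals, logistic regression, and Kaplan-Meier / log-rank survival
    analysis at 3-year, 5-year and total horizons.  Includes a calibrated
    synthetic-cohort generator for testing every pipeline stage without
    access to patient data, and a worked-example harness that
    reconstructs per-marker contingency tables from published summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
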