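Package: xylassay
Title: Analytical Validation and Method Comparison for Urinary D-Xylose Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical validation of an automatable enzymatic
    (xylose dehydrogenase, NADH photometry at 340 nm) urinary d-xylose assay
    and its statistical comparison against the manual phloroglucinol
    reference method. Implements single-point calibration, linearity
    fitting, detection-capability estimation (LoB, LoD, LoQ, LLoQ),
    selectivity and carry-over checks, within-run/between-run/total
    imprecision via one-way variance-component decomposition, iteratively
    reweighted Deming regression with jackknife confidence intervals,
    Bland-Altman agreement in absolute and percent-of-average modes,
    ROC-based cut-off transfer with DeLong confidence intervals, Cohen's
    kappa concordance, discrepancy adjudication, and seeded synthetic-data
    generators for every input table the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
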