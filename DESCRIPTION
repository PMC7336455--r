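Package: pdxgem
Title: Patient-Derived Xenograft Gene Expression Models of Drug Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds multi-gene drug-response predictors from patient-derived
    xenograft (PDX) panels. Pretreatment expression profiles are screened
    against post-treatment percent changes in tumor volume to find drug
    sensitivity biomarkers; candidates are then filtered by the concordance
    co-expression coefficient (CCEC), a Lin concordance correlation between a
    gene's co-expression neighborhood in the PDX panel and in a pretreatment
    cancer-patient cohort; a random-forest regressor trained on the surviving
    biomarkers scores independent patient cohorts, and predictions are
    evaluated with group tests, ROC AUC, and survival stratification. A
    block-structured simulator generates PDX panels and patient cohorts with
    controllable sensitivity signal and cross-system concordance for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
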