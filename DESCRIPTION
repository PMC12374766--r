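Package: habnet
Title: Discrete Bayesian Networks for Inpatient Mortality-Risk Analysis in
    Hereditary Angioedema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and querying discrete Bayesian networks over
    categorical inpatient cohort data, motivated by mortality-risk
    stratification of hereditary angioedema (ICD-10 D84.1) hospitalisations.
    Provides a configurable directed acyclic graph over demographic,
    socioeconomic, comorbidity and admission-severity variables;
    Dirichlet-conjugate (posterior-mean) estimation of conditional
    probability tables; exact inference by enumeration and by variable
    elimination under hard and virtual (soft) evidence; conditional
    risk sweeps and compound what-if scenarios reported as percentage-point
    deltas against a model baseline; a calibrated synthetic cohort generator
    for fully reproducible end-to-end testing; and train/test classification
    validation with confusion-matrix metrics and tie-aware ROC/AUC.
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
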