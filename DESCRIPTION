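Package: comornet
Title: Comorbidity Networks from General-Practitioner Prescription Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted, per-patient-normalized comorbidity networks from
    general-practitioner prescription (GPP) records carrying ICD-9-CM diagnosis
    codes. Diagnoses are pooled into the 20 ICD-9-CM chapter groups; co-prescription
    of two groups to the same patient on the same date creates a weighted link.
    Cohorts are stratified by sex, decade age class, prescription type and diabetes
    status (ICD-9 250.x drug prescriptions), networks are normalized by the number
    of patients in each stratum, and diabetic versus non-diabetic co-prescription
    rate ratios are estimated with exact Poisson (Garwood) confidence intervals.
    Includes a synthetic GPP generator with configurable group coupling so the
    whole pipeline is testable without access to confidential primary-care data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vctrs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
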