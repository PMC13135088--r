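Package: bctrisk
Title: Biomechanical CT Hip-Fracture Risk Scoring and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for opportunistic CT-based hip-fracture
    risk assessment. Extracts physical traits (trabecular/cortical BMD ratio,
    posterior subcutaneous fat thickness, gluteal muscle area, intramuscular fat
    fraction, femoral neck volume, hip width) from CT-like volumes; fits and
    calibrates a 0-100 logistic risk score with sex-specific prevalence matching
    against FRAX; evaluates discrimination with rank-based AUC, DeLong's paired
    test, sensitivity/specificity and diagnostic odds ratios at clinical
    thresholds; and estimates clinical effectiveness (positive predictive value
    and preventable fractures per 1000 tested). Includes parametric hip phantoms
    with closed-form ground truth and a case-cohort simulator so every stage is
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
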