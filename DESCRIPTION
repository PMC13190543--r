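Package: neoquant
Title: Targeted LC-MS/MS Urinary Biomonitoring of Neonicotinoids and
    Their Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A censoring-aware analysis pipeline for targeted
    isotope-dilution LC-MS/MS quantification of neonicotinoid
    insecticides and their metabolites in human urine.  Implements
    method-validation metrics (process efficiency, matrix effect,
    apparent recovery, 3-sigma/10-sigma detection and quantification
    limits with endogenous-background matrix selection, quality-control
    accuracy and precision), internal-standard calibration with weighted
    linear fits and mid-run stability checks, left-censored exposure
    quantification (half-LOD/half-LOQ substitution, creatinine
    adjustment, aggregate burden metrics, detection frequencies), and a
    nonparametric cohort-statistics layer (temporal trend tests,
    correlation matrices, cohort comparison, batch-effect assessment).
    A seeded synthetic peak-area generator emulates the statistical
    structure of validation experiments, batch run sequences, and
    biomonitoring cohorts so that every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
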