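Package: fhdx
Title: Molecular Diagnosis Workflows for Familial Hypercholesterolemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular-diagnostic workup of familial
    hypercholesterolemia cohorts: Dutch Lipid Clinic Network (DLCN) clinical
    scoring with Friedewald LDL-C estimation, rare-variant filtering of
    annotated variant tables (allele frequency, clinical assertions,
    predictor consensus, conservation percentiles), a data-driven ACMG/AMP
    evidence-combination engine, MLPA exon-dosage analysis with
    dosage-quotient normalization and HGVS deletion naming, cascade-screening
    planning over pedigrees, and cohort detection-yield summaries. Includes a
    synthetic-cohort generator and a deterministic reference fixture for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
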