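Package: hfpheno
Title: Multimorbidity Subgroup Discovery in Heart-Failure Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for identifying and characterizing
    multimorbidity subgroups in heart-failure cohorts from EHR-like tabular
    data: cohort identification from ICD-9 codes and diagnosis free text,
    mixed-type preprocessing (prevalence and missingness filters, chained
    ridge imputation, scaling), patient clustering via Gower distances with
    Ward linkage and via FAMD embeddings with Ward or K-means, internal
    validity indices with majority-vote model selection under a minimum
    cluster-size floor, per-cluster phenotypic disease networks, cluster
    profile tables with hypothesis tests, and Kaplan-Meier / Cox survival
    stratification of clusters by unplanned hospital admissions. Includes a
    synthetic cohort generator with planted cluster structure so every stage
    is testable without access-restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    igraph,
    survival,
    jsonlite,
    stringi
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
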