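#!/usr/bin/env Rscript
## Stage 5 — cluster characterization tables.
##
## Per-cluster summaries with across-cluster hypothesis tests: demographics,
## labs and comorbidities (median/IQR + Kruskal-Wallis for continuous,
## percentage + chi-square for binary), prescription-group prevalence and
## rates, and admission outcome summaries.

suppressPackageStartupMessages(library(hfpheno))

cohort <- read_cohort("results/cohort")
labels <- utils::read.csv("results/labels.csv")$label

chars <- summarize_clusters(cohort$patients, labels)
utils::write.csv(as.data.frame(chars), "results/profile_characteristics.csv",
                 row.names = FALSE)
n_sig <- sum(chars$significant, na.rm = TRUE)
message(sprintf("characteristics table: %d rows, %d significant at p < 0.05",
                nrow(chars), n_sig))

rx <- summarize_prescriptions(cohort$prescriptions, cohort$patients, labels,
                              observation_years = 2.5)
utils::write.csv(as.data.frame(rx), "results/profile_prescriptions.csv",
                 row.names = FALSE)

adm <- summarize_admissions(cohort$events, cohort$patients, labels,
                            horizon_years = 2.5)
utils::write.csv(as.data.frame(adm), "results/profile_admissions.csv",
                 row.names = FALSE)

message("wrote results/profile_{characteristics,prescriptions,admissions}.csv")
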