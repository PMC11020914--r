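#!/usr/bin/env Rscript
## Stage 1 — simulate the reference cohort.
##
## Draws the default four-subgroup synthetic heart-failure cohort (n = 2000):
## patients with demographics, 11 correlated comorbidity flags, labs with
## missingness, plus admission events and prescriptions, and writes the three
## CSV tables that every later stage reads.

suppressPackageStartupMessages(library(hfpheno))

seed <- 20260101L
spec <- default_cohort_spec(n_patients = 2000, seed = seed)
cohort <- simulate_cohort(spec)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

message(sprintf("simulated %d patients, %d admission events, %d prescriptions",
                nrow(cohort$patients), nrow(cohort$events),
                nrow(cohort$prescriptions)))
prev <- round(100 * colMeans(cohort$patients[, spec$comorbidity_names]), 1)
message("cohort comorbidity prevalence (%): ",
        paste(names(prev), prev, sep = "=", collapse = ", "))
message("wrote results/cohort/{patients,events,prescriptions}.csv")
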