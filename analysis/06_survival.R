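#!/usr/bin/env Rscript
## Stage 6 — survival stratification of the clusters.
##
## For each outcome (hospitalisation, emergency admission): per-cluster
## Kaplan-Meier curves from HF diagnosis, a K-group log-rank test, and the
## three Cox specifications (unadjusted; + age and gender; + NT-proBNP),
## with hazard ratios against the lowest-risk cluster.

suppressPackageStartupMessages(library(hfpheno))

cohort <- read_cohort("results/cohort")
labels <- utils::read.csv("results/labels.csv")$label
horizon <- 2.5
censor <- cohort$patients$hf_diagnosis_date + round(horizon * 365.25)

for (outcome in c("hospitalisation", "emergency")) {
  ds <- build_survival_dataset(cohort$patients, cohort$events, outcome,
                               censor, labels = labels)
  km <- do.call(rbind, lapply(sort(unique(labels)), function(g)
    cbind(cluster = g, kaplan_meier(ds, g))))
  utils::write.csv(km, sprintf("results/km_%s.csv", outcome), row.names = FALSE)

  lr <- logrank_test(ds)
  message(sprintf("%s: log-rank chi-square %.1f on %d df, p %s", outcome,
                  lr$statistic, lr$df,
                  format.pval(lr$p_value, digits = 3, eps = 1e-16)))

  cx <- cox_models(ds, models = 1:3)
  utils::write.csv(cbind(as.data.frame(cx), reference = attr(cx, "reference")),
                   sprintf("results/cox_%s.csv", outcome), row.names = FALSE)
  m1 <- cx[cx$model == 1 & grepl("cluster_f", cx$term), ]
  message(sprintf("  reference cluster %d; unadjusted HRs: %s",
                  attr(cx, "reference"),
                  paste(sprintf("%s %.2f (%.2f-%.2f)",
                                sub("cluster_f", "cluster ", m1$term),
                                m1$hr, m1$ci_lower, m1$ci_upper),
                        collapse = "; ")))
}
message("wrote results/km_*.csv and results/cox_*.csv")
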