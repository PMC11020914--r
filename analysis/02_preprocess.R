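#!/usr/bin/env Rscript
## Stage 2 — preprocessing.
##
## Applies the fixed preprocessing rules to the stored cohort: extract the
## clustering features, drop binary features below 2% prevalence and any
## feature above 40% missingness, impute the remaining missing lab cells by
## chained ridge regression. The unscaled matrix is written for the Gower
## pathway; scaling to z-scores / ±0.5 happens inside the clustering stage.

suppressPackageStartupMessages(library(hfpheno))

cohort <- read_cohort("results/cohort")
fm <- preprocess_cohort(cohort$patients, prevalence_min = 0.02,
                        missing_max = 0.40, scale = FALSE, seed = 11L)

utils::write.csv(cbind(patient_id = fm$patient_id, as.data.frame(fm$values)),
                 "results/features.csv", row.names = FALSE)
utils::write.csv(fm$audit, "results/feature_audit.csv", row.names = FALSE)

message(sprintf("kept %d features (%d continuous, %d binary); dropped %d",
                ncol(fm$values), sum(fm$meta$kind == "continuous"),
                sum(fm$meta$kind == "binary"), nrow(fm$audit)))
if (nrow(fm$audit)) {
  message("dropped: ", paste(fm$audit$name, " (", fm$audit$rule, ")",
                             sep = "", collapse = ", "))
}
message("wrote results/features.csv and results/feature_audit.csv")
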