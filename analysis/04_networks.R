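#!/usr/bin/env Rscript
## Stage 4 — phenotypic disease networks.
##
## Builds the whole-cohort PDN and one PDN per cluster from the binary
## comorbidity flags (edge = co-occurrence prevalence within the subset,
## 2% discard rule) and tabulates nodes, edges, average degree and the
## average clustering coefficient — the graph-level complexity measures of
## each subgroup's multimorbidity.

suppressPackageStartupMessages(library(hfpheno))

cohort <- read_cohort("results/cohort")
labels <- utils::read.csv("results/labels.csv")$label
diseases <- c("ICM", "CM", "HT", "Diabetes", "AF", "TIA",
              "VD", "CKD", "Anaemia", "COPD", "Obesity")

nets <- list(cohort = build_pdn(cohort$patients[, diseases], 0.02))
for (g in sort(unique(labels))) {
  nets[[paste0("cluster_", g)]] <-
    build_pdn(cohort$patients[labels == g, diseases], 0.02)
}

metrics <- data.frame(
  network = names(nets),
  n_patients = vapply(nets, function(x) x$n_patients, numeric(1)),
  n_nodes = vapply(nets, function(x) nrow(x$nodes), numeric(1)),
  n_edges = vapply(nets, function(x) nrow(x$edges), numeric(1)),
  average_degree = round(vapply(nets, average_degree, numeric(1)), 3),
  average_clustering = round(vapply(nets, average_clustering, numeric(1)), 3))
utils::write.csv(metrics, "results/network_metrics.csv", row.names = FALSE)
print(metrics, row.names = FALSE)

for (nm in names(nets)) export_network(nets[[nm]], file.path("results", paste0("pdn_", nm)))
message("wrote results/network_metrics.csv and results/pdn_* files (GraphML + CSV)")
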