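#' Configuration for the end-to-end subgrouping pipeline
#'
#' Bundles every stage's settings with a single global seed from which each
#' stage derives its own seed deterministically, so stages can be rerun in
#' isolation yet reproducibly.
#'
#' @param spec a [cohort_spec()] for simulation, or `NULL` to read an
#'   existing cohort from `input_dir`.
#' @param input_dir directory holding `patients.csv`/`events.csv`/
#'   `prescriptions.csv` when `spec` is `NULL`.
#' @param out_dir output directory for all stage artifacts.
#' @param prevalence_min,missing_max preprocessing filter thresholds.
#' @param methods clustering pathways to evaluate.
#' @param k_range candidate cluster counts.
#' @param size_floor admissibility floor (`NULL` = max(375, 10\% of n)).
#' @param prefer_k optional tie-break k for [majority_vote()].
#' @param edge_threshold PDN co-occurrence threshold.
#' @param outcomes event types for the survival stage.
#' @param horizon_years follow-up horizon for censoring.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = default_cohort_spec(),
                            input_dir = NULL,
                            out_dir = tempfile("hfpheno_run_"),
                            prevalence_min = 0.02,
                            missing_max = 0.40,
                            methods = c("gower_ward", "famd_ward", "famd_kmeans"),
                            k_range = 2:12,
                            size_floor = NULL,
                            prefer_k = NULL,
                            edge_threshold = 0.02,
                            outcomes = c("hospitalisation", "emergency"),
                            horizon_years = NULL,
                            seed = 1L) {
  stop_if_not(!is.null(spec) || !is.null(input_dir),
              "either a cohort spec or an input directory is required")
  stop_if_not(min(k_range) >= 2, "k_min must be at least 2")
  stop_if_not(prevalence_min >= 0 && prevalence_min <= 1, "invalid prevalence_min")
  stop_if_not(missing_max >= 0 && missing_max <= 1, "invalid missing_max")
  stop_if_not(edge_threshold >= 0 && edge_threshold <= 1, "invalid edge_threshold")
  structure(list(spec = spec, input_dir = input_dir, out_dir = out_dir,
                 prevalence_min = prevalence_min, missing_max = missing_max,
                 methods = methods, k_range = k_range,
                 size_floor = size_floor, prefer_k = prefer_k,
                 edge_threshold = edge_threshold, outcomes = outcomes,
                 horizon_years = horizon_years, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full subgrouping workflow
#'
#' Executes simulate/ingest, preprocessing, clustering evaluation,
#' majority-vote model selection, per-cluster disease networks, cluster
#' profile tables and the survival stage, writing every artifact as CSV
#' (networks also as GraphML) under `config$out_dir` together with a JSON
#' manifest of file MD5 hashes and the seeds used. Rerunning with the same
#' config and seed reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the main in-memory results: the cohort,
#'   feature matrix, selection report, chosen configuration, labels,
#'   networks, profiles, survival fits, and the manifest path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stop_if_not(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(paths) written <<- c(written, unname(paths))

  ## stage 1: simulate or ingest ------------------------------------------
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  cohort <- stage_wrap("ingest", {
    if (!is.null(config$spec)) {
      say("simulating cohort (n = %d)", config$spec$n_patients)
      simulate_cohort(config$spec)
    } else {
      say("reading cohort from %s", config$input_dir)
      read_cohort(config$input_dir)
    }
  })
  note(write_cohort(cohort, file.path(config$out_dir, "cohort")))
  horizon <- config$horizon_years %||% cohort$spec$censor_horizon %||% 2.5

  ## stage 2: preprocessing ------------------------------------------------
  fm <- stage_wrap("preprocess", preprocess_cohort(
    cohort$patients, prevalence_min = config$prevalence_min,
    missing_max = config$missing_max, scale = FALSE,
    seed = derive_seed(config$seed, 11L)))
  say("preprocessed: %d features kept, %d dropped", ncol(fm$values), nrow(fm$audit))
  p_feat <- file.path(config$out_dir, "features.csv")
  utils::write.csv(cbind(patient_id = fm$patient_id, as.data.frame(fm$values)),
                   p_feat, row.names = FALSE)
  p_audit <- file.path(config$out_dir, "feature_audit.csv")
  utils::write.csv(fm$audit, p_audit, row.names = FALSE)
  note(c(p_feat, p_audit))

  ## stage 3+4: clustering evaluation and model selection ------------------
  report <- stage_wrap("cluster", evaluate_clusterings(
    fm, methods = config$methods, k_range = config$k_range,
    seed = derive_seed(config$seed, 12L), size_floor = config$size_floor))
  p_rep <- file.path(config$out_dir, "selection_report.csv")
  utils::write.csv(as.data.frame(report), p_rep, row.names = FALSE)
  choice <- stage_wrap("select", majority_vote(report, prefer_k = config$prefer_k))
  say("selected %s with k = %d", choice$method, choice$k)
  p_choice <- file.path(config$out_dir, "chosen_configuration.json")
  jsonlite::write_json(list(method = choice$method, k = choice$k,
                            winners = as.list(choice$winners)),
                       p_choice, auto_unbox = TRUE, pretty = TRUE)
  labels <- choice$labels
  p_lab <- file.path(config$out_dir, "labels.csv")
  utils::write.csv(data.frame(patient_id = cohort$patients$patient_id,
                              method = choice$method, k = choice$k,
                              label = labels),
                   p_lab, row.names = FALSE)
  note(c(p_rep, p_choice, p_lab))

  ## stage 5: disease networks ---------------------------------------------
  comorb <- intersect(cohort$spec$comorbidity_names %||%
                        fm$meta$name[fm$meta$kind == "binary"],
                      names(cohort$patients))
  comorb <- setdiff(comorb, "gender")
  networks <- stage_wrap("network", {
    nets <- list(cohort = build_pdn(cohort$patients[, comorb, drop = FALSE],
                                    config$edge_threshold))
    for (g in sort(unique(labels))) {
      nets[[paste0("cluster_", g)]] <- build_pdn(
        cohort$patients[labels == g, comorb, drop = FALSE], config$edge_threshold)
    }
    nets
  })
  net_metrics <- data.frame(
    network = names(networks),
    n_nodes = vapply(networks, function(x) nrow(x$nodes), numeric(1)),
    n_edges = vapply(networks, function(x) nrow(x$edges), numeric(1)),
    average_degree = vapply(networks, average_degree, numeric(1)),
    average_clustering = vapply(networks, average_clustering, numeric(1)),
    stringsAsFactors = FALSE)
  p_met <- file.path(config$out_dir, "network_metrics.csv")
  utils::write.csv(net_metrics, p_met, row.names = FALSE)
  note(p_met)
  for (nm in names(networks)) {
    note(export_network(networks[[nm]], file.path(config$out_dir, paste0("pdn_", nm))))
  }

  ## stage 6: cluster profiles ---------------------------------------------
  profiles <- stage_wrap("profile", list(
    characteristics = summarize_clusters(cohort$patients, labels),
    prescriptions = summarize_prescriptions(cohort$prescriptions,
                                            cohort$patients, labels,
                                            observation_years = horizon),
    admissions = summarize_admissions(cohort$events, cohort$patients, labels,
                                      horizon_years = horizon)))
  for (nm in names(profiles)) {
    p <- file.path(config$out_dir, paste0("profile_", nm, ".csv"))
    utils::write.csv(as.data.frame(profiles[[nm]]), p, row.names = FALSE)
    note(p)
  }

  ## stage 7: survival -----------------------------------------------------
  censor <- cohort$patients$hf_diagnosis_date + round(horizon * 365.25)
  surv <- stage_wrap("survival", {
    out <- list()
    for (outcome in config$outcomes) {
      ds <- build_survival_dataset(cohort$patients, cohort$events, outcome,
                                   censor, labels = labels)
      km <- do.call(rbind, lapply(sort(unique(labels)), function(g)
        cbind(cluster = g, kaplan_meier(ds, g))))
      lr <- logrank_test(ds)
      cx <- cox_models(ds)
      out[[outcome]] <- list(dataset = ds, km = km, logrank = lr, cox = cx)
      p_km <- file.path(config$out_dir, paste0("km_", outcome, ".csv"))
      utils::write.csv(km, p_km, row.names = FALSE)
      p_cox <- file.path(config$out_dir, paste0("cox_", outcome, ".csv"))
      utils::write.csv(cbind(as.data.frame(cx),
                             reference = attr(cx, "reference")),
                       p_cox, row.names = FALSE)
      note(c(p_km, p_cox))
    }
    out
  })

  ## manifest --------------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    stage_seeds = list(preprocess = derive_seed(config$seed, 11L),
                       cluster = derive_seed(config$seed, 12L)),
    chosen = list(method = choice$method, k = choice$k),
    files = {
      h <- tools::md5sum(written[order(basename(written))])
      names(h) <- basename(names(h))
      as.list(h)
    })
  p_manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, pretty = TRUE)
  say("wrote %d artifacts to %s", length(written) + 1, config$out_dir)

  invisible(list(cohort = cohort, features = fm, report = report,
                 choice = choice, labels = labels, networks = networks,
                 net_metrics = net_metrics, profiles = profiles,
                 survival = surv, manifest = p_manifest))
}
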