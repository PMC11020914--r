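#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, p-value from the
#' chi-square distribution with (r-1)(c-1) df (wraps
#' `stats::chisq.test(correct = FALSE)`).
#'
#' @param contingency counts matrix (e.g. clusters x \{0,1\}).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_test <- function(contingency) {
  tab <- as.matrix(contingency)
  stop_if_not(all(tab >= 0), "counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stop_if_not(all(fit$expected > 0), "expected counts must be positive")
  list(statistic = unname(fit$statistic), p_value = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic, p-value from chi-square with (g-1) df (wraps
#' `stats::kruskal.test`).
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(length(groups) >= 2, "need at least two groups")
  stop_if_not(all(lengths(groups) > 0), "every group must be non-empty")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) {
    stop("all values identical across groups: zero rank variance", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::kruskal.test(pooled, g)
  list(statistic = unname(fit$statistic), p_value = unname(fit$p.value),
       df = unname(fit$parameter))
}

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

fmt_median_iqr <- function(x) {
  q <- median_iqr(x)
  sprintf("%.4g (%.4g-%.4g)", q["median"], q["q1"], q["q3"])
}

#' Per-cluster characterization table with across-cluster tests
#'
#' For each characteristic: continuous variables are summarized as median
#' (IQR, type-7 quantiles) per cluster and compared with a Kruskal-Wallis
#' test; binary variables as percentage per cluster with a chi-square test.
#' A whole-cohort column and a significance flag at p < 0.05 are included.
#'
#' @param patients one-row-per-patient data frame.
#' @param labels cluster labels aligned to `patients` rows.
#' @param continuous,binary variable names; defaults mirror
#'   [build_feature_matrix()].
#' @param alpha significance level (default 0.05).
#' @return a `profile_table` data frame: one row per characteristic,
#'   summary columns `cluster_1..k` and `overall`, plus numeric per-cluster
#'   value columns, `test`, `p_value`, `significant`.
#' @export
summarize_clusters <- function(patients, labels,
                               continuous = intersect(
                                 c("age", "bmi", "sodium", "urea", "creatinine",
                                   "hemoglobin", "rdw", "platelets", "ntprobnp"),
                                 names(patients)),
                               binary = setdiff(
                                 names(patients)[vapply(patients, is_binary_01, logical(1))],
                                 c("true_cluster", continuous)),
                               alpha = 0.05) {
  labels <- as.integer(labels)
  stop_if_not(length(labels) == nrow(patients), "labels must align with patients")
  groups <- sort(unique(labels))
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes == 0)) stop("cluster with zero patients", call. = FALSE)

  rows <- list()
  add_row <- function(var, kind, per_cluster, overall, test, p) {
    row <- data.frame(characteristic = var, kind = kind, stringsAsFactors = FALSE)
    for (i in seq_along(groups)) row[[paste0("cluster_", groups[i])]] <- per_cluster[i]
    row$overall <- overall
    row$test <- test
    row$p_value <- p
    row$significant <- p < alpha
    rows[[length(rows) + 1]] <<- row
  }

  add_row("n_patients", "count", as.numeric(sizes), length(labels), "", NA_real_)
  for (v in continuous) {
    x <- patients[[v]]
    per <- vapply(groups, function(g) median_iqr(x[labels == g])["median"], numeric(1))
    p <- kruskal_wallis(lapply(groups, function(g) x[labels == g & !is.na(x)]))$p_value
    add_row(v, "continuous", per, median_iqr(x)["median"], "kruskal_wallis", p)
  }
  for (v in binary) {
    x <- patients[[v]]
    per <- vapply(groups, function(g) 100 * mean(x[labels == g]), numeric(1))
    tab <- table(factor(labels, levels = groups), factor(x, levels = c(0, 1)))
    p <- tryCatch(chi_square_test(tab)$p_value, error = function(e) NA_real_)
    add_row(v, "binary_pct", per, 100 * mean(x), "chi_square", p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("profile_table", class(out))
  attr(out, "cluster_sizes") <- as.integer(sizes)
  out
}

#' Default mapping from drug identifier to pharmacological group
#'
#' Identity mapping over the HF-relevant groups the generator emits; a real
#' deployment supplies its own drug-to-group table.
#'
#' @return data.frame with columns `drug`, `group`.
#' @export
default_drug_groups <- function() {
  groups <- c("ACEi_ARB", "beta_blocker", "diuretic", "digoxin", "MRA",
              "anticoagulant", "antiplatelet", "statin", "bronchodilator")
  data.frame(drug = groups, group = groups, stringsAsFactors = FALSE)
}

#' Per-cluster prescription summaries
#'
#' For every pharmacological group and cluster: the percentage of patients
#' with at least one prescription in the group, the mean per-patient
#' prescriptions per year, and a chi-square test of the at-least-one
#' prevalence across clusters. Unmapped drug identifiers are mapped to
#' `"other"` with a warning.
#'
#' @param prescriptions data frame with `patient_id` and `drug_group` (or
#'   `drug`) columns.
#' @param patients one-row-per-patient data frame (`patient_id`).
#' @param labels cluster labels aligned to `patients`.
#' @param drug_map data frame `drug` -> `group`; default
#'   [default_drug_groups()].
#' @param observation_years person-time denominator for rates.
#' @return a `profile_table` data frame (rows = group x measure).
#' @export
summarize_prescriptions <- function(prescriptions, patients, labels,
                                    drug_map = default_drug_groups(),
                                    observation_years = 2.5) {
  labels <- as.integer(labels)
  groups <- sort(unique(labels))
  drug_col <- if ("drug_group" %in% names(prescriptions)) "drug_group" else "drug"
  drug <- prescriptions[[drug_col]]
  grp <- drug_map$group[match(drug, drug_map$drug)]
  if (anyNA(grp) && length(grp)) {
    warning(sprintf("%d prescription rows with unmapped drugs mapped to 'other'",
                    sum(is.na(grp))))
    grp[is.na(grp)] <- "other"
  }
  all_groups <- sort(unique(c(drug_map$group, grp)))

  rows <- list()
  for (g in all_groups) {
    pid <- prescriptions$patient_id[grp == g]
    has <- patients$patient_id %in% pid
    n_rx <- tabulate(factor(pid, levels = patients$patient_id),
                     nbins = nrow(patients))
    pct <- vapply(groups, function(cl) 100 * mean(has[labels == cl]), numeric(1))
    rate <- vapply(groups, function(cl)
      mean(n_rx[labels == cl] / observation_years), numeric(1))
    tab <- table(factor(labels, levels = groups), factor(has, levels = c(FALSE, TRUE)))
    p <- tryCatch(chi_square_test(tab)$p_value, error = function(e) NA_real_)
    row <- data.frame(characteristic = g, kind = "pct_any", stringsAsFactors = FALSE)
    for (i in seq_along(groups)) row[[paste0("cluster_", groups[i])]] <- pct[i]
    row$overall <- 100 * mean(has)
    row$test <- "chi_square"
    row$p_value <- p
    row$significant <- !is.na(p) && p < 0.05
    rows[[length(rows) + 1]] <- row
    row2 <- data.frame(characteristic = g, kind = "rx_per_year", stringsAsFactors = FALSE)
    for (i in seq_along(groups)) row2[[paste0("cluster_", groups[i])]] <- rate[i]
    row2$overall <- mean(n_rx / observation_years)
    row2$test <- ""
    row2$p_value <- NA_real_
    row2$significant <- NA
    rows[[length(rows) + 1]] <- row2
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("profile_table", class(out))
  out
}

#' Per-cluster admission outcome summaries
#'
#' For each cluster and event type: median (IQR) events per patient-year,
#' the percentage of patients with an event within one year of HF
#' diagnosis, and within the whole observation period. Events dated at or
#' before diagnosis are excluded with a warning. Person-years run from
#' diagnosis to the censor date.
#'
#' @param events data frame: `patient_id`, `event_type`, `event_date`.
#' @param patients data frame with `patient_id`, `hf_diagnosis_date`.
#' @param labels cluster labels aligned to `patients`.
#' @param censor_date scalar `Date`, or per-patient vector; default
#'   diagnosis + `horizon_years`.
#' @param horizon_years follow-up used when `censor_date` is `NULL`.
#' @return a `profile_table` data frame.
#' @export
summarize_admissions <- function(events, patients, labels,
                                 censor_date = NULL, horizon_years = 2.5) {
  labels <- as.integer(labels)
  groups <- sort(unique(labels))
  if (is.null(censor_date)) {
    censor_date <- patients$hf_diagnosis_date + round(horizon_years * 365.25)
  }
  if (length(censor_date) == 1) censor_date <- rep(censor_date, nrow(patients))
  py <- years_between(patients$hf_diagnosis_date, censor_date)
  stop_if_not(all(py > 0), "censor date precedes an HF diagnosis date")

  dx <- patients$hf_diagnosis_date[match(events$patient_id, patients$patient_id)]
  bad <- events$event_date <= dx
  if (any(bad)) {
    warning(sprintf("%d events at or before HF diagnosis excluded", sum(bad)))
    events <- events[!bad, , drop = FALSE]
    dx <- dx[!bad]
  }
  t_ev <- years_between(dx, events$event_date)

  types <- sort(unique(events$event_type))
  if (!length(types)) types <- c("emergency", "hospitalisation")
  rows <- list()
  for (type in types) {
    sel <- events$event_type == type
    pid <- factor(events$patient_id[sel], levels = patients$patient_id)
    n_ev <- tabulate(pid, nbins = nrow(patients))
    rate <- n_ev / py
    within1 <- patients$patient_id %in% events$patient_id[sel & t_ev <= 1]
    ever <- n_ev > 0
    for (meas in c("events_per_year_median", "pct_within_1y", "pct_within_period")) {
      vals <- switch(meas,
        events_per_year_median = vapply(groups, function(cl)
          median_iqr(rate[labels == cl])["median"], numeric(1)),
        pct_within_1y = vapply(groups, function(cl)
          100 * mean(within1[labels == cl]), numeric(1)),
        pct_within_period = vapply(groups, function(cl)
          100 * mean(ever[labels == cl]), numeric(1)))
      overall <- switch(meas,
        events_per_year_median = median_iqr(rate)["median"],
        pct_within_1y = 100 * mean(within1),
        pct_within_period = 100 * mean(ever))
      row <- data.frame(characteristic = paste(type, meas, sep = "."),
                        kind = meas, stringsAsFactors = FALSE)
      for (i in seq_along(groups)) row[[paste0("cluster_", groups[i])]] <- vals[i]
      row$overall <- overall
      row$test <- ""
      row$p_value <- NA_real_
      row$significant <- NA
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("profile_table", class(out))
  out
}
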