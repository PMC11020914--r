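#' Assemble a time-to-first-event dataset for one outcome
#'
#' All patients are aligned at the moment of HF diagnosis. Duration is the
#' time in years to the first qualifying event, or to the censor date for
#' patients without one (event flag 0). Events dated at or before diagnosis
#' are excluded with a warning. Covariates (age, gender, NT-proBNP when
#' present) and cluster labels travel with the rows.
#'
#' @param patients data frame with `patient_id`, `hf_diagnosis_date` and
#'   covariate columns.
#' @param events data frame with `patient_id`, `event_type`, `event_date`.
#' @param outcome_type event type to analyse (e.g. `"hospitalisation"`).
#' @param censor_date scalar administrative censor `Date`, or a per-patient
#'   vector (e.g. diagnosis + fixed horizon).
#' @param labels optional cluster labels aligned to `patients`.
#' @return a `survival_dataset` data frame: `patient_id`, `duration`
#'   (years, > 0), `event` (0/1), covariates, `cluster`.
#' @export
build_survival_dataset <- function(patients, events, outcome_type,
                                   censor_date, labels = NULL) {
  stop_if_not(all(!is.na(patients$hf_diagnosis_date)),
              "every patient needs an HF diagnosis date")
  if (length(censor_date) == 1) censor_date <- rep(censor_date, nrow(patients))
  stop_if_not(length(censor_date) == nrow(patients),
              "censor_date must be scalar or one per patient")
  late <- censor_date <= patients$hf_diagnosis_date
  if (any(late)) {
    stop(sprintf("censor date at or before diagnosis for: %s",
                 paste(utils::head(patients$patient_id[late], 5), collapse = ", ")),
         call. = FALSE)
  }
  ev <- events[events$event_type == outcome_type, , drop = FALSE]
  dx <- patients$hf_diagnosis_date[match(ev$patient_id, patients$patient_id)]
  bad <- ev$event_date <= dx
  if (any(bad)) {
    warning(sprintf("%d '%s' events at or before diagnosis excluded",
                    sum(bad), outcome_type))
    ev <- ev[!bad, , drop = FALSE]
  }
  first <- tapply(as.numeric(ev$event_date), ev$patient_id, min)
  first_date <- as.Date(as.numeric(first[patients$patient_id]),
                        origin = "1970-01-01")
  has_event <- !is.na(first_date) & first_date <= censor_date
  end <- ifelse(has_event, as.numeric(first_date), as.numeric(censor_date))
  duration <- years_between(patients$hf_diagnosis_date,
                            as.Date(end, origin = "1970-01-01"))

  out <- data.frame(patient_id = patients$patient_id,
                    duration = duration,
                    event = as.integer(has_event),
                    stringsAsFactors = FALSE)
  for (v in intersect(c("age", "gender", "ntprobnp"), names(patients))) {
    out[[v]] <- patients[[v]]
  }
  if (!is.null(labels)) out$cluster <- as.integer(labels)
  attr(out, "outcome_type") <- outcome_type
  class(out) <- c("survival_dataset", class(out))
  out
}

#' Kaplan-Meier curve for a patient group
#'
#' Product-limit estimator with Greenwood confidence band (log transform),
#' via `survival::survfit`.
#'
#' @param data a `survival_dataset`.
#' @param group a cluster id, or `"all"` for the whole cohort.
#' @return data frame: `time`, `n_risk`, `n_event`, `survival`, `lower`,
#'   `upper`.
#' @export
kaplan_meier <- function(data, group = "all") {
  if (!identical(group, "all")) {
    data <- data[data$cluster == group, , drop = FALSE]
    stop_if_not(nrow(data) > 0, "no patients in group '%s'", group)
  }
  fit <- survival::survfit(survival::Surv(duration, event) ~ 1, data = data,
                           conf.type = "log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' K-group log-rank test across clusters
#'
#' @param data a `survival_dataset` with a `cluster` column (or `labels`
#'   supplied).
#' @param labels optional cluster labels overriding `data$cluster`.
#' @return list with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(data, labels = NULL) {
  if (!is.null(labels)) data$cluster <- as.integer(labels)
  stop_if_not(!is.null(data$cluster), "cluster labels required")
  stop_if_not(length(unique(data$cluster)) >= 2, "need at least two groups")
  at_risk <- tapply(data$duration, data$cluster, sum)
  if (any(at_risk <= 0)) stop("a group has zero at-risk time", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(duration, event) ~ cluster, data = data)
  df <- length(fit$n) - 1
  list(statistic = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' The three Cox proportional-hazards specifications
#'
#' Model 1 enters cluster membership alone (dummies against the reference
#' cluster); Model 2 adds age and gender; Model 3 adds NT-proBNP. The
#' reference cluster is the one with the lowest percentage of observed
#' outcomes (the lowest-risk cluster), so hazard ratios read as risk
#' relative to it. Partial-likelihood fits use Efron tie handling
#' (`survival::coxph`).
#'
#' @param data a `survival_dataset` with `cluster` (and `age`, `gender`,
#'   `ntprobnp` for models 2-3).
#' @param models subset of 1:3.
#' @param reference `"lowest_risk"` (default) or an explicit cluster id.
#' @return a `cox_fits` data frame: `model`, `term`, `coef`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, with the reference cluster id in
#'   `attr(, "reference")`.
#' @export
cox_models <- function(data, models = 1:3, reference = "lowest_risk") {
  stop_if_not(!is.null(data$cluster), "cluster labels required")
  stop_if_not(all(models %in% 1:3), "models must be a subset of 1:3")
  ev_pct <- tapply(data$event, data$cluster, mean)
  ref <- if (identical(reference, "lowest_risk")) {
    as.integer(names(ev_pct)[which.min(ev_pct)])
  } else {
    as.integer(reference)
  }
  data$cluster_f <- stats::relevel(factor(data$cluster), ref = as.character(ref))

  covars <- list(`1` = "cluster_f",
                 `2` = c("cluster_f", "age", "gender"),
                 `3` = c("cluster_f", "age", "gender", "ntprobnp"))
  rows <- list()
  for (m in models) {
    vars <- covars[[as.character(m)]]
    # constant covariates carry no information for the partial likelihood;
    # drop them rather than fail
    keep <- vapply(vars, function(v)
      v == "cluster_f" || isTRUE(stats::var(data[[v]], na.rm = TRUE) > 0),
      logical(1))
    vars <- vars[keep]
    f <- stats::as.formula(paste("survival::Surv(duration, event) ~",
                                 paste(vars, collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = "efron")
    if (!is.null(fit$info) && any(is.na(stats::coef(fit)))) {
      stop(sprintf("model %d did not converge", m), call. = FALSE)
    }
    sm <- summary(fit)
    ci <- sm$conf.int
    rows[[length(rows) + 1]] <- data.frame(
      model = m,
      term = rownames(sm$coefficients),
      coef = sm$coefficients[, "coef"],
      hr = sm$coefficients[, "exp(coef)"],
      ci_lower = ci[, "lower .95"],
      ci_upper = ci[, "upper .95"],
      p_value = sm$coefficients[, "Pr(>|z|)"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- ref
  class(out) <- c("cox_fits", class(out))
  out
}
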