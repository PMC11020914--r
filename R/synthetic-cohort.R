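#' Generate a synthetic EHR-like heart-failure cohort
#'
#' Draws one row per patient: cluster assignment (kept in the hidden
#' `true_cluster` column, never part of the clustering input), demographics,
#' correlated binary comorbidity flags, and continuous labs with the
#' configured missingness. Comorbidity co-occurrence uses a Gaussian copula:
#' a latent multivariate normal with the cluster's correlation matrix is
#' thresholded at each disease's marginal quantile, so marginal prevalences
#' are exact targets while pairwise co-occurrence is controlled by the
#' latent correlation.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `hf_cohort`: a list with data frames
#'   `patients`, `events` (empty until [generate_events()]), and
#'   `prescriptions` (empty until [generate_prescriptions()]), plus the
#'   generating `spec`.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, 1L))
  n <- spec$n_patients
  k <- spec$n_clusters
  d <- length(spec$comorbidity_names)

  cl <- sample.int(k, n, replace = TRUE, prob = spec$mixing_proportions)

  age <- spec$age_specs$mean[cl] + spec$age_specs$sd[cl] * stats::rnorm(n)
  gender <- as.integer(stats::runif(n) < spec$female_prob[cl])  # 1 = female

  flags <- matrix(0L, n, d, dimnames = list(NULL, spec$comorbidity_names))
  for (g in seq_len(k)) {
    idx <- which(cl == g)
    if (!length(idx)) next
    R <- spec$copula_correlation[[g]]
    L <- tryCatch(chol(R + diag(1e-10, d)), error = function(e)
      stop(sprintf("copula_correlation for cluster %d is not positive semi-definite", g),
           call. = FALSE))
    Z <- matrix(stats::rnorm(length(idx) * d), ncol = d) %*% L
    thr <- stats::qnorm(pmin(pmax(spec$prevalence_matrix[g, ], 0), 1))
    flags[idx, ] <- 1L * sweep(Z, 2, thr, "<")
  }

  labs <- list()
  for (nm in names(spec$lab_specs)) {
    ls <- spec$lab_specs[[nm]]
    x <- ls$mean[cl] + ls$sd[cl] * stats::rnorm(n)
    if (ls$missing_rate > 0) {
      if (spec$missing_mechanism == "MAR") {
        # missingness logistic in age, centred so the average rate stays
        # close to the configured one
        za <- (age - mean(age)) / max(stats::sd(age), 1e-9)
        p <- stats::plogis(stats::qlogis(ls$missing_rate) + 0.5 * za)
      } else {
        p <- ls$missing_rate
      }
      x[stats::runif(n) < p] <- NA_real_
    }
    labs[[nm]] <- x
  }

  dx_start <- as.Date("2013-01-01")
  dx_end <- as.Date("2019-06-30")
  hf_diagnosis_date <- dx_start +
    floor(stats::runif(n) * (as.numeric(dx_end - dx_start) + 1))

  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    true_cluster = cl,
    age = age,
    gender = gender,
    stringsAsFactors = FALSE)
  for (nm in names(labs)) patients[[nm]] <- labs[[nm]]
  patients <- cbind(patients, as.data.frame(flags))
  patients$hf_diagnosis_date <- hf_diagnosis_date

  structure(list(patients = patients,
                 events = empty_events(),
                 prescriptions = empty_prescriptions(),
                 spec = spec),
            class = "hf_cohort")
}

empty_events <- function() {
  data.frame(patient_id = character(), event_type = character(),
             event_date = as.Date(character()), years_from_dx = numeric(),
             stringsAsFactors = FALSE)
}

empty_prescriptions <- function() {
  data.frame(patient_id = character(), drug_group = character(),
             date = as.Date(character()), stringsAsFactors = FALSE)
}

#' Simulate unplanned-admission events for a synthetic cohort
#'
#' For each patient and outcome type, event times after HF diagnosis follow
#' a homogeneous Poisson process with rate `baseline_rate *
#' hazard_multipliers[[outcome]][true_cluster]`, so the first-event time is
#' exponential with that rate — the constant-hazard design under which Cox
#' proportional hazards holds exactly. Arrivals beyond the censoring horizon
#' are discarded; a patient whose first arrival falls beyond the horizon has
#' no event row (administratively censored).
#'
#' @param cohort an `hf_cohort` from [generate_cohort()].
#' @param spec optional `cohort_spec`; defaults to the one stored in
#'   `cohort`.
#' @return the cohort with its `events` table filled.
#' @export
generate_events <- function(cohort, spec = cohort$spec) {
  stop_if_not(inherits(cohort, "hf_cohort"), "cohort must be an hf_cohort")
  stop_if_not(spec$baseline_rate > 0, "baseline_rate must be positive")
  set.seed(derive_seed(spec$seed, 2L))
  pts <- cohort$patients
  n <- nrow(pts)
  h <- spec$censor_horizon
  rows <- list()
  for (out in names(spec$hazard_multipliers)) {
    rate <- spec$baseline_rate * spec$hazard_multipliers[[out]][pts$true_cluster]
    n_ev <- stats::rpois(n, rate * h)
    tot <- sum(n_ev)
    if (tot == 0) next
    # given the count, Poisson arrival times are sorted uniforms on (0, h)
    times <- stats::runif(tot, 0, h)
    pid <- rep(pts$patient_id, n_ev)
    dx <- rep(pts$hf_diagnosis_date, n_ev)
    o <- order(pid, times)
    rows[[out]] <- data.frame(
      patient_id = pid[o],
      event_type = out,
      # ceiling keeps every event date strictly after the diagnosis date
      event_date = dx[o] + ceiling(times[o] * 365.25),
      years_from_dx = times[o],
      stringsAsFactors = FALSE)
  }
  cohort$events <- if (length(rows)) do.call(rbind, rows) else empty_events()
  rownames(cohort$events) <- NULL
  cohort
}

## default per-cluster probability of at least one prescription per drug
## group; qualitative only (high-burden clusters receive more HF therapy)
default_prescription_probs <- function(n_clusters) {
  groups <- c("ACEi_ARB", "beta_blocker", "diuretic", "digoxin", "MRA",
              "anticoagulant", "antiplatelet", "statin", "bronchodilator")
  base <- c(0.55, 0.60, 0.75, 0.15, 0.25, 0.45, 0.35, 0.50, 0.20)
  mult <- seq(1.2, 0.6, length.out = n_clusters)
  probs <- outer(mult, base)
  colnames(probs) <- groups
  pmin(probs, 0.95)
}

#' Simulate prescriptions for a synthetic cohort
#'
#' Each patient receives, per pharmacological group, at least one
#' prescription with a cluster-dependent probability; prescribing patients
#' get `1 + Poisson(2)` prescriptions dated uniformly over the follow-up
#' window.
#'
#' @inheritParams generate_events
#' @param probs optional `n_clusters x n_groups` matrix of at-least-one
#'   probabilities (columns named by drug group).
#' @return the cohort with its `prescriptions` table filled.
#' @export
generate_prescriptions <- function(cohort, spec = cohort$spec,
                                   probs = default_prescription_probs(spec$n_clusters)) {
  stop_if_not(inherits(cohort, "hf_cohort"), "cohort must be an hf_cohort")
  set.seed(derive_seed(spec$seed, 3L))
  pts <- cohort$patients
  n <- nrow(pts)
  h <- spec$censor_horizon
  rows <- list()
  for (grp in colnames(probs)) {
    has <- stats::runif(n) < probs[pts$true_cluster, grp]
    idx <- which(has)
    if (!length(idx)) next
    counts <- 1L + stats::rpois(length(idx), 2)
    pid <- rep(pts$patient_id[idx], counts)
    dx <- rep(pts$hf_diagnosis_date[idx], counts)
    times <- stats::runif(sum(counts), 0, h)
    rows[[grp]] <- data.frame(
      patient_id = pid, drug_group = grp,
      date = dx + round(times * 365.25), stringsAsFactors = FALSE)
  }
  presc <- if (length(rows)) do.call(rbind, rows) else empty_prescriptions()
  o <- order(presc$patient_id, presc$drug_group, presc$date)
  cohort$prescriptions <- presc[o, , drop = FALSE]
  rownames(cohort$prescriptions) <- NULL
  cohort
}

#' Generate a complete synthetic cohort (patients, events, prescriptions)
#'
#' @param spec a [cohort_spec()]; defaults to [default_cohort_spec()].
#' @return an `hf_cohort` with all three tables filled.
#' @export
simulate_cohort <- function(spec = default_cohort_spec()) {
  generate_prescriptions(generate_events(generate_cohort(spec)))
}

#' Write / read a cohort as plain CSV files
#'
#' `write_cohort()` writes `patients.csv`, `events.csv` and
#' `prescriptions.csv` into `dir`; `read_cohort()` reads them back. Dates
#' round-trip as ISO strings.
#'
#' @param cohort an `hf_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` an `hf_cohort` (without a `spec`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "events.csv", "prescriptions.csv"))
  utils::write.csv(cohort$patients, paths[1], row.names = FALSE)
  utils::write.csv(cohort$events, paths[2], row.names = FALSE)
  utils::write.csv(cohort$prescriptions, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pts <- utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  pts$hf_diagnosis_date <- as.Date(pts$hf_diagnosis_date)
  ev <- utils::read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE,
                        colClasses = c(event_date = "Date"))
  pr <- utils::read.csv(file.path(dir, "prescriptions.csv"), stringsAsFactors = FALSE,
                        colClasses = c(date = "Date"))
  structure(list(patients = pts, events = ev, prescriptions = pr, spec = NULL),
            class = "hf_cohort")
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat(sprintf("<hf_cohort> %d patients, %d event rows, %d prescription rows\n",
              nrow(x$patients), nrow(x$events), nrow(x$prescriptions)))
  invisible(x)
}
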