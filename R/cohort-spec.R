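#' Specification of a synthetic heart-failure cohort
#'
#' A `cohort_spec` fixes every parameter of the synthetic generator: cluster
#' mixing proportions, per-cluster comorbidity prevalences with a Gaussian
#' copula governing co-occurrence, per-cluster lab means/sds with missingness
#' rates, demographics, and cluster-dependent admission hazards. All
#' generator defaults are stand-ins: the study cohort they emulate is
#' access-restricted hospital EHR data, so no default here is an estimate of
#' a real population quantity.
#'
#' @param n_patients number of patients to generate.
#' @param n_clusters number of planted subgroups.
#' @param mixing_proportions length-`n_clusters` simplex vector.
#' @param comorbidity_names disease labels; columns of `prevalence_matrix`.
#' @param prevalence_matrix `n_clusters x n_diseases` Bernoulli marginals in
#'   \[0,1\].
#' @param copula_correlation a single correlation matrix, or a list of one
#'   per cluster, driving latent-normal comorbidity co-occurrence. Must be
#'   symmetric positive semi-definite with unit diagonal.
#' @param lab_specs named list; each element a list with `mean` and `sd`
#'   (length `n_clusters` each) and scalar `missing_rate` in \[0,1\].
#' @param age_specs list with `mean` and `sd`, length `n_clusters` each.
#' @param female_prob per-cluster probability of female gender.
#' @param hazard_multipliers named list (one element per outcome type, e.g.
#'   `hospitalisation`, `emergency`) of per-cluster positive multipliers.
#' @param baseline_rate events per patient-year for a multiplier of 1.
#' @param censor_horizon follow-up length in years after HF diagnosis.
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`; under MAR the
#'   missingness probability is logistic in age with the configured rate as
#'   the cohort-average.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return an object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_patients,
                        n_clusters,
                        mixing_proportions = rep(1 / n_clusters, n_clusters),
                        comorbidity_names,
                        prevalence_matrix,
                        copula_correlation = diag(length(comorbidity_names)),
                        lab_specs = list(),
                        age_specs = list(mean = rep(80, n_clusters), sd = rep(8, n_clusters)),
                        female_prob = rep(0.5, n_clusters),
                        hazard_multipliers = list(hospitalisation = rep(1, n_clusters),
                                                  emergency = rep(1, n_clusters)),
                        baseline_rate = 0.2,
                        censor_horizon = 2.5,
                        missing_mechanism = c("MCAR", "MAR"),
                        seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  prevalence_matrix <- as.matrix(prevalence_matrix)
  colnames(prevalence_matrix) <- comorbidity_names
  if (!is.list(copula_correlation) || is.matrix(copula_correlation)) {
    copula_correlation <- rep(list(as.matrix(copula_correlation)), n_clusters)
  }
  spec <- structure(list(
    n_patients = as.integer(n_patients),
    n_clusters = as.integer(n_clusters),
    mixing_proportions = mixing_proportions,
    comorbidity_names = comorbidity_names,
    prevalence_matrix = prevalence_matrix,
    copula_correlation = copula_correlation,
    lab_specs = lab_specs,
    age_specs = age_specs,
    female_prob = female_prob,
    hazard_multipliers = hazard_multipliers,
    baseline_rate = baseline_rate,
    censor_horizon = censor_horizon,
    missing_mechanism = missing_mechanism,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(spec) {
  stop_if_not(spec$n_patients >= 1, "n_patients must be positive")
  stop_if_not(spec$n_clusters >= 1, "n_clusters must be positive")
  stop_if_not(length(spec$mixing_proportions) == spec$n_clusters,
              "mixing_proportions must have length n_clusters")
  stop_if_not(all(spec$mixing_proportions >= 0) &&
                abs(sum(spec$mixing_proportions) - 1) <= 1e-9,
              "mixing_proportions must be a simplex vector (nonnegative, summing to 1)")
  stop_if_not(nrow(spec$prevalence_matrix) == spec$n_clusters,
              "prevalence_matrix must have one row per cluster")
  stop_if_not(ncol(spec$prevalence_matrix) == length(spec$comorbidity_names),
              "prevalence_matrix must have one column per comorbidity")
  stop_if_not(all(spec$prevalence_matrix >= 0 & spec$prevalence_matrix <= 1),
              "prevalences must lie in [0, 1]")
  stop_if_not(length(spec$copula_correlation) == spec$n_clusters,
              "copula_correlation must have one matrix per cluster")
  d <- length(spec$comorbidity_names)
  for (g in seq_len(spec$n_clusters)) {
    R <- spec$copula_correlation[[g]]
    stop_if_not(is.matrix(R) && all(dim(R) == d),
                "copula_correlation for cluster %d has wrong dimension", g)
    stop_if_not(max(abs(R - t(R))) < 1e-12,
                "copula_correlation for cluster %d is not symmetric", g)
    stop_if_not(max(abs(diag(R) - 1)) < 1e-12,
                "copula_correlation for cluster %d must have unit diagonal", g)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop(sprintf("copula_correlation for cluster %d is not positive semi-definite", g),
           call. = FALSE)
    }
  }
  for (nm in names(spec$lab_specs)) {
    ls <- spec$lab_specs[[nm]]
    stop_if_not(length(ls$mean) == spec$n_clusters && length(ls$sd) == spec$n_clusters,
                "lab '%s' must give a mean and sd per cluster", nm)
    stop_if_not(all(ls$sd >= 0), "lab '%s' has a negative sd", nm)
    stop_if_not(ls$missing_rate >= 0 && ls$missing_rate <= 1,
                "lab '%s' missing_rate must lie in [0, 1]", nm)
  }
  stop_if_not(all(spec$female_prob >= 0 & spec$female_prob <= 1),
              "female_prob must lie in [0, 1]")
  for (out in names(spec$hazard_multipliers)) {
    hm <- spec$hazard_multipliers[[out]]
    stop_if_not(length(hm) == spec$n_clusters,
                "hazard multipliers for '%s' must have length n_clusters", out)
    stop_if_not(all(hm >= 0), "hazard multipliers for '%s' must be nonnegative", out)
  }
  stop_if_not(spec$baseline_rate > 0, "baseline_rate must be positive")
  stop_if_not(spec$censor_horizon > 0, "censor_horizon must be positive")
  spec
}

#' Default four-cluster synthetic heart-failure cohort
#'
#' Ships the package's reference simulation: four subgroups whose comorbidity
#' prevalence vectors follow the qualitative pattern reported for real
#' heart-failure multimorbidity clusters — a high-burden cluster with
#' near-universal anaemia, prevalent CKD and hypertension and the highest
#' NT-proBNP; a hypertension/AF/obesity cluster; a large anaemia-dominant
#' cluster with otherwise low burden; and a younger low-burden cluster —
#' with contrasts of at least 0.6 on the distinguishing diseases and lab
#' shifts of at least 2 sd (hemoglobin, NT-proBNP), so planted structure is
#' recoverable by the clustering pipeline. All values are synthetic
#' stand-ins, not estimates from any real cohort.
#'
#' @param n_patients cohort size (default 2000).
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(n_patients = 2000, seed = 20260101L) {
  diseases <- c("ICM", "CM", "HT", "Diabetes", "AF", "TIA",
                "VD", "CKD", "Anaemia", "COPD", "Obesity")
  prev <- rbind(
    c(0.88, 0.05, 0.85, 0.85, 0.85, 0.10, 0.12, 0.92, 0.93, 0.10, 0.10),
    c(0.10, 0.05, 0.95, 0.08, 0.80, 0.08, 0.10, 0.08, 0.05, 0.08, 0.75),
    c(0.06, 0.02, 0.20, 0.04, 0.08, 0.04, 0.05, 0.08, 0.97, 0.04, 0.05),
    c(0.05, 0.03, 0.10, 0.02, 0.06, 0.02, 0.04, 0.02, 0.03, 0.03, 0.06))
  colnames(prev) <- diseases
  exch <- function(rho, d) {
    R <- matrix(rho, d, d)
    diag(R) <- 1
    R
  }
  labs <- list(
    bmi        = list(mean = c(25.0, 30.0, 24.3, 23.0), sd = c(1.6, 1.5, 1.6, 1.6),
                      missing_rate = 0.25),
    sodium     = list(mean = c(140, 140, 139.6, 139.5), sd = c(2.0, 2.0, 2.0, 2.0),
                      missing_rate = 0.10),
    urea       = list(mean = c(68, 48, 44, 42), sd = c(8, 5, 5, 4),
                      missing_rate = 0.10),
    creatinine = list(mean = c(1.5, 1.0, 0.98, 0.92), sd = c(0.15, 0.08, 0.08, 0.07),
                      missing_rate = 0.10),
    hemoglobin = list(mean = c(10.8, 13.3, 11.6, 14.1), sd = c(0.6, 0.55, 0.6, 0.5),
                      missing_rate = 0.15),
    rdw        = list(mean = c(15.7, 14.3, 15.1, 14.1), sd = c(0.5, 0.4, 0.45, 0.4),
                      missing_rate = 0.20),
    platelets  = list(mean = c(215, 215, 225, 280), sd = c(30, 28, 28, 25),
                      missing_rate = 0.15),
    ntprobnp   = list(mean = c(3800, 1500, 2800, 650), sd = c(400, 250, 350, 150),
                      missing_rate = 0.35))
  cohort_spec(
    n_patients = n_patients,
    n_clusters = 4,
    mixing_proportions = c(0.22, 0.23, 0.32, 0.23),
    comorbidity_names = diseases,
    prevalence_matrix = prev,
    copula_correlation = list(exch(0.10, 11), exch(0.10, 11),
                              exch(0.10, 11), exch(0.10, 11)),
    lab_specs = labs,
    age_specs = list(mean = c(80, 79, 85, 61), sd = c(3, 3, 3, 3)),
    female_prob = c(0.20, 0.62, 0.38, 0.88),
    hazard_multipliers = list(hospitalisation = c(5.9, 2.8, 2.4, 1.0),
                              emergency = c(2.7, 2.0, 1.3, 1.0)),
    baseline_rate = 0.18,
    censor_horizon = 2.5,
    seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients, %d clusters, %d comorbidities, %d labs\n",
              x$n_patients, x$n_clusters, length(x$comorbidity_names),
              length(x$lab_specs)))
  cat("  mixing:", paste(format(x$mixing_proportions), collapse = " "), "\n")
  cat("  outcomes:", paste(names(x$hazard_multipliers), collapse = ", "),
      sprintf("(baseline %.3g / patient-year, horizon %.3g y)\n",
              x$baseline_rate, x$censor_horizon))
  invisible(x)
}
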