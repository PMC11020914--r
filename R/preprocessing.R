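#' ICD-9 code prefixes and free-text keywords for HF cohort identification
#'
#' The default prefixes are the heart-failure ICD-9-CM families (428,
#' hypertensive heart/kidney disease with HF, and the 425.4-425.9
#' cardiomyopathies), stored undotted so both dotted and undotted code
#' dialects match after normalization. Keywords are the Portuguese names and
#' abbreviations of heart failure plus the NYHA staging mention; matching is
#' case- and diacritic-insensitive so accented and unaccented spellings are
#' equivalent.
#'
#' @return a character vector.
#' @export
hf_icd9_codes <- function() {
  c("428", "39891", "40201", "40291", "40401", "40403",
    "40411", "40413", "40491", "40493",
    "4254", "4255", "4256", "4257", "4258", "4259")
}

#' @rdname hf_icd9_codes
#' @export
hf_keywords <- function() {
  c("Insuficiência cardíaca", "ICFEp", "ICFEr", "IC", "ICC", "NYHA")
}

normalize_code <- function(x) gsub(".", "", x, fixed = TRUE)

fold_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

#' Identify heart-failure patients from diagnosis records
#'
#' A patient enters the cohort if any of their records carries an ICD-9 code
#' matching one of the code prefixes (after stripping dots from both sides),
#' or a free-text diagnosis containing one of the keywords
#' (case-insensitive and diacritic-insensitive substring match).
#'
#' @param records data frame with columns `patient_id`, `icd9_code`,
#'   `free_text` (either field may be empty per record).
#' @param codes code prefixes; default [hf_icd9_codes()].
#' @param keywords free-text keywords; default [hf_keywords()].
#' @return sorted character vector of matching patient ids.
#' @export
identify_hf_patients <- function(records, codes = hf_icd9_codes(),
                                 keywords = hf_keywords()) {
  stop_if_not(length(codes) + length(keywords) > 0,
              "at least one code prefix or keyword is required")
  code <- normalize_code(ifelse(is.na(records$icd9_code), "", records$icd9_code))
  code_hit <- rep(FALSE, nrow(records))
  for (p in normalize_code(codes)) {
    code_hit <- code_hit | (nzchar(code) & startsWith(code, p))
  }
  txt <- fold_text(ifelse(is.na(records$free_text), "", records$free_text))
  text_hit <- rep(FALSE, nrow(records))
  for (kw in fold_text(keywords)) {
    text_hit <- text_hit | stringi::stri_detect_fixed(txt, kw)
  }
  sort(unique(records$patient_id[code_hit | text_hit]))
}

#' Aggregate longitudinal observations to one row per patient
#'
#' Labs and BMI become the mean over all observations (missing if a patient
#' has none); age is taken at the last observation date; comorbidity flags
#' are ever-present (1 if flagged at any visit). Aggregating over the full
#' history rather than the latest value guards against a single anomalous
#' recent measurement dominating a patient's profile.
#'
#' @param observations long data frame: `patient_id`, `obs_date`, optional
#'   `age`, lab columns (may be NA per visit), binary flag columns.
#' @param labs names of columns to mean-aggregate.
#' @param flags names of binary columns to OR-aggregate.
#' @return one-row-per-patient data frame.
#' @export
aggregate_patient_features <- function(observations,
                                       labs = intersect(
                                         c("bmi", "sodium", "urea", "creatinine",
                                           "hemoglobin", "rdw", "platelets", "ntprobnp"),
                                         names(observations)),
                                       flags = names(observations)[
                                         vapply(observations, is_binary_01, logical(1))]) {
  stop_if_not(all(c("patient_id", "obs_date") %in% names(observations)),
              "observations need patient_id and obs_date columns")
  flags <- setdiff(flags, c(labs, "patient_id", "obs_date", "age"))
  ids <- unique(observations$patient_id)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(observations)), observations$patient_id)[ids]
  if ("age" %in% names(observations)) {
    out$age <- vapply(idx, function(i) {
      i <- i[!is.na(observations$age[i])]
      if (!length(i)) return(NA_real_)
      observations$age[i[which.max(as.numeric(observations$obs_date[i]))]]
    }, numeric(1))
  }
  for (nm in labs) {
    out[[nm]] <- vapply(idx, function(i) {
      v <- observations[[nm]][i]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  for (nm in flags) {
    out[[nm]] <- vapply(idx, function(i)
      as.numeric(any(observations[[nm]][i] == 1, na.rm = TRUE)), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Drop rare binary features and heavily missing features
#'
#' Binary features with cohort prevalence strictly below `prevalence_min`
#' are removed, then any feature with a missing fraction strictly above
#' `missing_max` is removed — both inequalities strict, so a feature exactly
#' at a threshold is kept. Dropped columns are appended to the matrix's
#' audit log.
#'
#' @param fm a [feature_matrix()].
#' @param prevalence_min minimum binary prevalence (default 0.02).
#' @param missing_max maximum missing fraction (default 0.40).
#' @return the filtered `feature_matrix`.
#' @export
filter_features <- function(fm, prevalence_min = 0.02, missing_max = 0.40) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  audit <- fm$audit

  prev <- vapply(seq_len(ncol(fm$values)), function(j) {
    if (fm$meta$kind[j] != "binary") return(NA_real_)
    v <- fm$values[, j]
    if (all(v %in% c(-0.5, 0.5))) mean(v == 0.5) else mean(v == 1)
  }, numeric(1))
  drop_prev <- which(fm$meta$kind == "binary" & prev < prevalence_min)
  if (length(drop_prev)) {
    audit <- rbind(audit, data.frame(name = fm$meta$name[drop_prev],
                                     rule = "prevalence_min",
                                     value = prev[drop_prev],
                                     stringsAsFactors = FALSE))
    fm$values <- fm$values[, -drop_prev, drop = FALSE]
    fm$meta <- fm$meta[-drop_prev, , drop = FALSE]
  }

  miss <- colMeans(is.na(fm$values))
  drop_miss <- which(miss > missing_max)
  if (length(drop_miss)) {
    audit <- rbind(audit, data.frame(name = fm$meta$name[drop_miss],
                                     rule = "missing_max",
                                     value = miss[drop_miss],
                                     stringsAsFactors = FALSE))
    fm$values <- fm$values[, -drop_miss, drop = FALSE]
    fm$meta <- fm$meta[-drop_miss, , drop = FALSE]
  }

  if (ncol(fm$values) == 0) stop("all feature columns were dropped by the filters",
                                 call. = FALSE)
  rownames(fm$meta) <- NULL
  fm$audit <- audit
  fm
}

#' Chained-equation imputation with ridge regressors
#'
#' Missing cells of each incomplete column are modelled as a linear (ridge)
#' function of all other columns, round-robin, iterated until the largest
#' absolute change of any imputed cell falls below `tol` or `max_iter`
#' passes. Missing cells start at the column mean; observed cells are never
#' touched. The ridge penalty is a small multiple of the average predictor
#' scale, there purely for numerical stability under collinearity.
#'
#' @param fm a [feature_matrix()]; binary columns must be complete.
#' @param max_iter maximum sweeps (default 10).
#' @param tol convergence tolerance on imputed cells (default 1e-3).
#' @param seed integer; kept for interface stability — the sweep order is
#'   deterministic so the result does not depend on it.
#' @return a `feature_matrix` with no missing cells.
#' @export
impute_chained <- function(fm, max_iter = 10, tol = 1e-3, seed = 1L) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  X <- fm$values
  miss <- is.na(X)
  all_missing <- colnames(X)[colSums(miss) == nrow(X)]
  if (length(all_missing)) {
    stop(sprintf("column(s) entirely missing: %s (filter them first)",
                 paste(all_missing, collapse = ", ")), call. = FALSE)
  }
  incomplete <- which(colSums(miss) > 0)
  if (!length(incomplete)) return(fm)

  for (j in incomplete) X[miss[, j], j] <- mean(X[!miss[, j], j])

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in incomplete) {
      obs <- !miss[, j]
      Xo <- cbind(1, X[obs, -j, drop = FALSE])
      Xm <- cbind(1, X[!obs, -j, drop = FALSE])
      XtX <- crossprod(Xo)
      lambda <- 1e-8 * mean(diag(XtX)[-1])
      pen <- diag(c(0, rep(max(lambda, 1e-12), ncol(Xo) - 1)))
      beta <- solve(XtX + pen, crossprod(Xo, X[obs, j]))
      new <- drop(Xm %*% beta)
      delta <- max(delta, max(abs(new - X[!obs, j])))
      X[!obs, j] <- new
    }
    if (delta < tol) break
  }
  fm$values <- X
  fm$meta$missing_frac_imputed <- colMeans(miss)
  fm
}

#' Scale features for clustering
#'
#' Continuous columns are z-scored to mean 0 and (population) sd 1; binary
#' columns are shifted from \{0,1\} to \{-0.5,+0.5\}. Already-scaled columns
#' pass through unchanged, so the operation is idempotent.
#'
#' @param fm a [feature_matrix()] with no missing cells.
#' @return the scaled `feature_matrix` (`scaling` metadata updated).
#' @export
scale_features <- function(fm) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  stop_if_not(!anyNA(fm$values), "impute before scaling: missing cells present")
  for (j in seq_len(ncol(fm$values))) {
    v <- fm$values[, j]
    if (fm$meta$kind[j] == "continuous") {
      s <- sd_pop(v)
      if (s < 1e-12) {
        stop(sprintf("continuous column '%s' has zero variance", fm$meta$name[j]),
             call. = FALSE)
      }
      fm$values[, j] <- (v - mean(v)) / s
      fm$meta$scaling[j] <- "zscore"
    } else {
      if (all(v %in% c(-0.5, 0.5))) {
        # already half-shifted
      } else if (all(v %in% c(0, 1))) {
        fm$values[, j] <- v - 0.5
      } else {
        stop(sprintf("binary column '%s' is neither 0/1 nor half-shifted",
                     fm$meta$name[j]), call. = FALSE)
      }
      fm$meta$scaling[j] <- "halfshift"
    }
  }
  fm
}

#' Full preprocessing chain: extract, filter, impute, scale
#'
#' Runs [build_feature_matrix()], [filter_features()], [impute_chained()]
#' and optionally [scale_features()] in the fixed order the workflow
#' prescribes (prevalence filter before missingness filter, imputation
#' before scaling).
#'
#' @param patients one-row-per-patient data frame.
#' @param prevalence_min,missing_max filter thresholds.
#' @param scale if `FALSE`, stop before scaling (the Gower pathway consumes
#'   unscaled features — range normalization inside the Gower formula makes
#'   pre-scaling redundant).
#' @param seed passed to [impute_chained()].
#' @return a `feature_matrix`.
#' @export
preprocess_cohort <- function(patients, prevalence_min = 0.02,
                              missing_max = 0.40, scale = TRUE, seed = 1L) {
  fm <- build_feature_matrix(patients)
  fm <- filter_features(fm, prevalence_min, missing_max)
  fm <- impute_chained(fm, seed = seed)
  if (scale) fm <- scale_features(fm)
  fm
}
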