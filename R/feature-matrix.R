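#' Clustering feature matrix with column metadata
#'
#' A light container pairing a numeric patients-by-features matrix (missing
#' values allowed before imputation) with per-column metadata: the feature
#' kind (`continuous` or `binary`), the scaling applied so far, and the
#' original prevalence / missing fraction. Filters append to an `audit`
#' table recording every dropped column and the rule that dropped it.
#'
#' @param values numeric matrix, patients in rows, named feature columns.
#' @param kinds character vector, `"continuous"` or `"binary"` per column.
#' @param patient_id optional row identifiers.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kinds, patient_id = rownames(values)) {
  values <- as.matrix(values)
  stop_if_not(!is.null(colnames(values)), "values must have column names")
  stop_if_not(length(kinds) == ncol(values), "one kind per column required")
  stop_if_not(all(kinds %in% c("continuous", "binary")),
              "kinds must be 'continuous' or 'binary'")
  for (j in which(kinds == "binary")) {
    v <- values[, j]
    stop_if_not(!anyNA(v), "binary column '%s' has missing values", colnames(values)[j])
    stop_if_not(is_binary_01(v), "binary column '%s' is not 0/1", colnames(values)[j])
  }
  meta <- data.frame(
    name = colnames(values),
    kind = kinds,
    scaling = "none",
    prevalence = vapply(seq_len(ncol(values)), function(j)
      if (kinds[j] == "binary") mean(values[, j] == 1) else NA_real_, numeric(1)),
    missing_frac = colMeans(is.na(values)),
    stringsAsFactors = FALSE)
  structure(list(values = values, meta = meta,
                 patient_id = patient_id,
                 audit = data.frame(name = character(), rule = character(),
                                    value = numeric(), stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' Extract the clustering input from a cohort
#'
#' Selects age, gender, the labs and the comorbidity flags from the
#' patients table; `true_cluster`, identifiers and dates are never part of
#' the clustering input.
#'
#' @param patients a patients data frame (one row per patient).
#' @param continuous names of continuous columns present in `patients`.
#' @param binary names of binary columns present in `patients`.
#' @return a `feature_matrix`.
#' @export
build_feature_matrix <- function(patients,
                                 continuous = intersect(
                                   c("age", "bmi", "sodium", "urea", "creatinine",
                                     "hemoglobin", "rdw", "platelets", "ntprobnp"),
                                   names(patients)),
                                 binary = setdiff(
                                   names(patients)[vapply(patients, is_binary_01, logical(1))],
                                   c("true_cluster", continuous))) {
  cols <- c(continuous, binary)
  stop_if_not(length(cols) > 0, "no feature columns found")
  vals <- as.matrix(patients[, cols, drop = FALSE])
  rownames(vals) <- patients$patient_id
  feature_matrix(vals,
                 kinds = c(rep("continuous", length(continuous)),
                           rep("binary", length(binary))),
                 patient_id = patients$patient_id)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (%d continuous, %d binary)\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$kind == "continuous"), sum(x$meta$kind == "binary")))
  if (nrow(x$audit)) cat(sprintf("  %d columns dropped by filters\n", nrow(x$audit)))
  invisible(x)
}
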