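#' Gower dissimilarity matrix for mixed-type features
#'
#' For records x, y over m features, the dissimilarity is the weighted mean
#' of per-feature contributions
#' \deqn{d_G(x,y) = \sum_j w_j f_j(x_j,y_j) / \sum_j w_j}
#' with \eqn{f_j = |x_j - y_j| / r_j} for interval features (\eqn{r_j} the
#' feature's observed range) and \eqn{f_j = 1[x_j \ne y_j]} for categorical
#' features. With unit weights every entry lies in \[0,1\], the diagonal is
#' exactly 0 and the matrix is symmetric. Binary comorbidity flags are
#' treated as categorical (match/mismatch), and the input should be the
#' unscaled feature matrix — the range normalization inside the formula
#' makes prior z-scoring redundant.
#'
#' @param fm a [feature_matrix()] with no missing cells, or a plain numeric
#'   matrix accompanied by `kinds`.
#' @param weights nonnegative feature weights, default 1 for every feature.
#' @param kinds per-column `"continuous"`/`"binary"` when `fm` is a plain
#'   matrix.
#' @return an n x n symmetric matrix of class `gower_dist` with zero
#'   diagonal.
#' @export
gower_matrix <- function(fm, weights = NULL, kinds = NULL) {
  if (inherits(fm, "feature_matrix")) {
    X <- fm$values
    kinds <- fm$meta$kind
  } else {
    X <- as.matrix(fm)
    stop_if_not(!is.null(kinds), "kinds required for a plain matrix input")
  }
  stop_if_not(!anyNA(X), "missing cells: impute before computing distances")
  m <- ncol(X)
  if (is.null(weights)) weights <- rep(1, m)
  stop_if_not(length(weights) == m, "one weight per feature required")
  stop_if_not(all(weights >= 0), "weights must be nonnegative")
  stop_if_not(any(weights > 0), "all feature weights are zero")

  n <- nrow(X)
  D <- matrix(0, n, n)
  for (j in seq_len(m)) {
    if (weights[j] == 0) next
    x <- X[, j]
    if (kinds[j] == "continuous") {
      r <- max(x) - min(x)
      if (r <= 0) {
        stop(sprintf("interval feature '%s' has zero range", colnames(X)[j]),
             call. = FALSE)
      }
      D <- D + (weights[j] / r) * abs(outer(x, x, "-"))
    } else {
      D <- D + weights[j] * (outer(x, x, "!=") * 1)
    }
  }
  D <- D / sum(weights)
  dimnames(D) <- list(rownames(X), rownames(X))
  class(D) <- c("gower_dist", class(D))
  D
}
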