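#' Factor analysis of mixed data (FAMD) embedding
#'
#' Principal-component embedding that acts as PCA on quantitative columns
#' and as MCA on qualitative ones. Continuous columns are z-scored
#' (population sd); each level of a categorical/binary column becomes an
#' indicator divided by the square root of the level's proportion, then
#' centred; the combined matrix is factored by truncated SVD and patients
#' get their principal coordinates. Component signs are fixed by the
#' largest-absolute-loading-positive convention so embeddings are
#' reproducible across platforms.
#'
#' @param fm a [feature_matrix()] (scaled or not — columns are re-derived
#'   from the stored kinds), no missing cells.
#' @param n_components number of components, or `NULL` to keep the smallest
#'   number explaining at least `var_target` of total inertia.
#' @param var_target fraction of inertia to retain when `n_components` is
#'   `NULL` (default 0.8).
#' @return an object of class `famd_embedding`: list with `scores`
#'   (patients x components), `loadings`, `eig` (inertia per component),
#'   `prop_var`.
#' @export
famd_embed <- function(fm, n_components = NULL, var_target = 0.8) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  stop_if_not(!anyNA(fm$values), "missing cells: impute before embedding")
  n <- nrow(fm$values)
  blocks <- list()
  block_names <- character()
  for (j in seq_len(ncol(fm$values))) {
    v <- fm$values[, j]
    nm <- fm$meta$name[j]
    if (fm$meta$kind[j] == "continuous") {
      s <- sd_pop(v)
      stop_if_not(s > 1e-12, "continuous column '%s' has zero variance", nm)
      blocks[[length(blocks) + 1]] <- matrix((v - mean(v)) / s, ncol = 1)
      block_names <- c(block_names, nm)
    } else {
      lev <- sort(unique(v))
      stop_if_not(length(lev) >= 2, "binary column '%s' is constant", nm)
      for (l in lev) {
        ind <- as.numeric(v == l)
        p <- mean(ind)
        col <- ind / sqrt(p)
        blocks[[length(blocks) + 1]] <- matrix(col - mean(col), ncol = 1)
        block_names <- c(block_names, paste0(nm, "=", l))
      }
    }
  }
  Z <- do.call(cbind, blocks)
  colnames(Z) <- block_names

  sv <- svd(Z)
  pos <- sv$d > max(sv$d) * 1e-10
  rank <- sum(pos)
  eig <- sv$d^2
  prop <- eig / sum(eig)
  if (is.null(n_components)) {
    n_components <- which(cumsum(prop) >= var_target)[1]
    if (is.na(n_components)) n_components <- rank
  }
  stop_if_not(n_components >= 1 && n_components <= rank,
              "n_components must lie in [1, rank] (rank = %d)", rank)

  U <- sv$u[, seq_len(n_components), drop = FALSE]
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  d <- sv$d[seq_len(n_components)]
  for (c in seq_len(n_components)) {
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) {
      V[, c] <- -V[, c]
      U[, c] <- -U[, c]
    }
  }
  scores <- U %*% diag(d, n_components)
  dimnames(scores) <- list(rownames(fm$values),
                           paste0("Dim", seq_len(n_components)))
  dimnames(V) <- list(block_names, colnames(scores))
  structure(list(scores = scores, loadings = V,
                 eig = eig[seq_len(n_components)],
                 prop_var = prop[seq_len(n_components)],
                 rank = rank),
            class = "famd_embedding")
}

#' @export
print.famd_embedding <- function(x, ...) {
  cat(sprintf("<famd_embedding> %d patients x %d components (%.1f%% of inertia)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$prop_var)))
  invisible(x)
}
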