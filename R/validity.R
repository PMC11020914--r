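#' Mean silhouette width from a precomputed dissimilarity
#'
#' For each point, `a` is its mean dissimilarity to the other members of its
#' cluster and `b` the smallest mean dissimilarity to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`, with members of singleton clusters
#' contributing 0. Higher is better. For the Gower pathway the input is the
#' Gower matrix; FAMD pathways use Euclidean distances in embedding space.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param labels integer cluster labels, k >= 2 non-empty clusters.
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(d, labels) {
  D <- if (inherits(d, "dist")) as.matrix(d) else unclass(as.matrix(d))
  labels <- as.integer(factor(labels))
  n <- length(labels)
  stop_if_not(nrow(D) == n, "labels must align with the dissimilarity matrix")
  k <- length(unique(labels))
  stop_if_not(k >= 2, "silhouette needs at least two clusters")
  M <- stats::model.matrix(~ 0 + factor(labels))
  sizes <- colSums(M)
  S <- D %*% M                               # total dissimilarity to each cluster
  own <- cbind(seq_len(n), labels)
  a <- S[own] / pmax(sizes[labels] - 1, 1)
  Smean <- sweep(S, 2, sizes, "/")
  Smean[own] <- Inf
  b <- apply(Smean, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  s[!is.finite(s)] <- 0
  mean(s)
}

cluster_centroids <- function(X, labels) {
  X <- as.matrix(X)
  groups <- sort(unique(labels))
  t(vapply(groups, function(g) colMeans(X[labels == g, , drop = FALSE]),
           numeric(ncol(X))))
}

#' Calinski-Harabasz index (variance-ratio criterion)
#'
#' `[tr(B)/(k-1)] / [tr(W)/(n-k)]` with B and W the between- and
#' within-cluster dispersion matrices of a numeric representation. Higher is
#' better. Needs coordinates, not a bare dissimilarity: for the Gower
#' pathway the scaled feature matrix stands in (see the package vignette).
#'
#' @param X numeric matrix (patients x features) or `famd_embedding`.
#' @param labels integer cluster labels.
#' @return nonnegative real.
#' @export
calinski_harabasz <- function(X, labels) {
  if (inherits(X, "famd_embedding")) X <- X$scores
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X)
  k <- length(unique(labels))
  stop_if_not(k >= 2, "index needs at least two clusters")
  stop_if_not(k < n, "k = n leaves no within-cluster degrees of freedom")
  grand <- colMeans(X)
  cent <- cluster_centroids(X, labels)
  sizes <- as.integer(table(labels))
  trB <- sum(sizes * rowSums(sweep(cent, 2, grand)^2))
  trW <- sum((X - cent[labels, , drop = FALSE])^2)
  if (trW <= .Machine$double.eps * trB) {
    stop("zero within-cluster dispersion: index diverges", call. = FALSE)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity
#' `(s_i + s_j) / d_ij` to another cluster, where `s` is the mean Euclidean
#' distance of members to their centroid and `d_ij` the centroid distance.
#' Lower is better.
#'
#' @inheritParams calinski_harabasz
#' @return nonnegative real.
#' @export
davies_bouldin <- function(X, labels) {
  if (inherits(X, "famd_embedding")) X <- X$scores
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  stop_if_not(k >= 2, "index needs at least two clusters")
  cent <- cluster_centroids(X, labels)
  s <- vapply(seq_len(k), function(g) {
    mean(sqrt(rowSums(sweep(X[labels == g, , drop = FALSE], 2, cent[g, ])^2)))
  }, numeric(1))
  dmat <- as.matrix(stats::dist(cent))
  if (any(dmat[upper.tri(dmat)] < 1e-12)) {
    stop("duplicate cluster centroids: index undefined", call. = FALSE)
  }
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / dmat[i, j], numeric(1)))
  }, numeric(1))
  mean(r)
}
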