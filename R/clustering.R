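new_clustering_result <- function(method, k, labels) {
  sizes <- table(labels)
  structure(list(method = method, k = as.integer(k),
                 labels = as.integer(labels),
                 sizes = as.integer(sizes)),
            class = "clustering_result")
}

## relabel so cluster 1 is the largest; ties broken by first appearance
relabel_by_size <- function(labels) {
  tab <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  o <- order(-tab, first[names(tab)])
  map <- stats::setNames(seq_along(o), names(tab)[o])
  as.integer(map[as.character(labels)])
}

#' Ward hierarchical clustering on a precomputed dissimilarity
#'
#' Agglomerates with the Lance-Williams Ward recursion
#' (`stats::hclust(method = "ward.D2")`) and cuts the dendrogram at `k`
#' clusters. For the Gower pathway the input is the Gower matrix; for the
#' FAMD pathway, Euclidean distances in embedding space. Ward's
#' within-variance objective is exact only for Euclidean input, so its use
#' on Gower dissimilarities is heuristic — the standard pairing for
#' mixed-type EHR data, kept here deliberately. Cluster ids are 1..k,
#' ordered by decreasing cluster size.
#'
#' @param d a dissimilarity: `gower_dist`/square matrix, `dist`, a
#'   `famd_embedding`, or a numeric matrix of coordinates (rows = patients).
#' @param k number of clusters (2..n).
#' @return a `clustering_result` with a `hclust` attribute carrying the
#'   full tree.
#' @export
ward_cluster <- function(d, k) {
  if (inherits(d, "famd_embedding")) d <- stats::dist(d$scores)
  if (is.matrix(d) && nrow(d) == ncol(d) &&
      (inherits(d, "gower_dist") || isTRUE(all.equal(d, t(d), tolerance = 1e-8)))) {
    d <- stats::as.dist(d)
  } else if (is.matrix(d)) {
    d <- stats::dist(d)
  }
  stop_if_not(inherits(d, "dist"), "d must be a dissimilarity or coordinate matrix")
  n <- attr(d, "Size")
  stop_if_not(k >= 2, "k must be at least 2")
  stop_if_not(k <= n, "k = %d exceeds the number of patients (%d)", k, n)
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- relabel_by_size(stats::cutree(tree, k = k))
  res <- new_clustering_result(method = "ward", k = k, labels = labels)
  attr(res, "tree") <- tree
  res
}

#' K-means clustering of an embedding
#'
#' Lloyd-style K-means (`stats::kmeans`, Hartigan-Wong) with `n_init`
#' random restarts, keeping the solution with the lowest within-cluster sum
#' of squares; deterministic given `seed`. Cluster ids are 1..k ordered by
#' decreasing size.
#'
#' @param embedding a `famd_embedding` or numeric matrix (rows = patients).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @param max_iter iteration cap per restart (default 300).
#' @return a `clustering_result`.
#' @export
kmeans_cluster <- function(embedding, k, seed = 1L, n_init = 10, max_iter = 300) {
  X <- if (inherits(embedding, "famd_embedding")) embedding$scores else as.matrix(embedding)
  n_distinct <- nrow(unique(X))
  stop_if_not(k >= 2, "k must be at least 2")
  stop_if_not(k <= n_distinct,
              "k = %d exceeds the number of distinct rows (%d)", k, n_distinct)
  set.seed(seed)
  fit <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = max_iter)
  labels <- relabel_by_size(fit$cluster)
  res <- new_clustering_result(method = "kmeans", k = k, labels = labels)
  attr(res, "tot_withinss") <- fit$tot.withinss
  res
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> method=%s k=%d sizes=[%s]\n",
              x$method, x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}
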