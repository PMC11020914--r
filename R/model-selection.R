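resolve_size_floor <- function(size_floor, n) {
  if (is.null(size_floor)) return(max(375, ceiling(0.10 * n)))
  if (size_floor < 1) return(ceiling(size_floor * n))
  as.integer(size_floor)
}

#' Score every (method, k) clustering configuration
#'
#' Runs the three pathways — Gower + Ward, FAMD + Ward, FAMD + K-means —
#' over a range of k and scores each configuration with the mean silhouette
#' width, the Calinski-Harabasz index and the Davies-Bouldin index.
#' Silhouette uses the Gower matrix for the Gower pathway and Euclidean
#' embedding distances for the FAMD pathways; Calinski-Harabasz and
#' Davies-Bouldin require coordinates, so the Gower pathway is scored on the
#' scaled feature matrix.
#'
#' @param fm a preprocessed, unscaled [feature_matrix()] (no missing cells).
#' @param methods subset of `c("gower_ward", "famd_ward", "famd_kmeans")`.
#' @param k_range candidate cluster counts (default 2:12).
#' @param seed integer seed (used by the K-means restarts).
#' @param size_floor minimum admissible cluster size: `NULL` for the
#'   default `max(375, 10%% of n)` stability floor, a fraction of n, or an
#'   absolute count. A configuration is admissible only if its smallest
#'   cluster is strictly larger than the floor... see [majority_vote()].
#' @param n_components FAMD components (`NULL`: smallest number explaining
#'   80\% of inertia).
#' @return a `selection_report`: data frame with one row per configuration
#'   (method, k, the three indices, min cluster size, admissible flag) and
#'   the label vectors in `attr(, "labels")`.
#' @export
evaluate_clusterings <- function(fm,
                                 methods = c("gower_ward", "famd_ward", "famd_kmeans"),
                                 k_range = 2:12,
                                 seed = 1L,
                                 size_floor = NULL,
                                 n_components = NULL) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  stop_if_not(all(methods %in% c("gower_ward", "famd_ward", "famd_kmeans")),
              "unknown method name")
  n <- nrow(fm$values)
  floor_n <- resolve_size_floor(size_floor, n)
  fm_scaled <- scale_features(fm)

  need_gower <- "gower_ward" %in% methods
  need_famd <- any(c("famd_ward", "famd_kmeans") %in% methods)
  D_gower <- if (need_gower) gower_matrix(fm) else NULL
  emb <- if (need_famd) famd_embed(fm_scaled, n_components = n_components) else NULL
  D_emb <- if (need_famd) as.matrix(stats::dist(emb$scores)) else NULL

  rows <- list()
  labels_store <- list()
  for (method in methods) {
    tree_labels <- switch(method,
      gower_ward = {
        res <- attr(ward_cluster(D_gower, k = 2), "tree")
        function(k) relabel_by_size(stats::cutree(res, k = k))
      },
      famd_ward = {
        res <- attr(ward_cluster(emb, k = 2), "tree")
        function(k) relabel_by_size(stats::cutree(res, k = k))
      },
      famd_kmeans = function(k)
        kmeans_cluster(emb, k, seed = derive_seed(seed, 100L + k))$labels)
    for (k in k_range) {
      labels <- tree_labels(k)
      sil_d <- if (method == "gower_ward") D_gower else D_emb
      rep_x <- if (method == "gower_ward") fm_scaled$values else emb$scores
      rows[[length(rows) + 1]] <- data.frame(
        method = method, k = k,
        silhouette = silhouette_score(sil_d, labels),
        calinski_harabasz = calinski_harabasz(rep_x, labels),
        davies_bouldin = davies_bouldin(rep_x, labels),
        min_cluster_size = min(table(labels)),
        stringsAsFactors = FALSE)
      labels_store[[paste(method, k, sep = "_")]] <- labels
    }
  }
  report <- do.call(rbind, rows)
  report$admissible <- report$min_cluster_size > floor_n
  attr(report, "labels") <- labels_store
  attr(report, "n") <- n
  attr(report, "size_floor") <- floor_n
  class(report) <- c("selection_report", class(report))
  report
}

#' Choose the clustering configuration by majority vote of validity indices
#'
#' Configurations whose smallest cluster does not exceed the size floor are
#' removed; then each index nominates its best admissible configuration
#' (higher-better for silhouette and Calinski-Harabasz, lower-better for
#' Davies-Bouldin) and the configuration nominated by at least two of the
#' three indices wins. A three-way split is an error carrying the full
#' tally, unless `prefer_k` names an admissible k to break the tie — a
#' stand-in for the clinical-interpretability judgement a formal rule
#' cannot capture.
#'
#' @param report a `selection_report` from [evaluate_clusterings()].
#' @param size_floor overrides the report's floor if not `NULL` (absolute
#'   count, or fraction of n).
#' @param prefer_k optional k used only to resolve a three-way tie.
#' @return list with `method`, `k`, `winners` (per-index nominations),
#'   `tally`, and the admissible report rows.
#' @export
majority_vote <- function(report, size_floor = NULL, prefer_k = NULL) {
  n <- attr(report, "n") %||% NA_integer_
  floor_n <- if (is.null(size_floor)) {
    attr(report, "size_floor") %||% resolve_size_floor(NULL, n)
  } else {
    resolve_size_floor(size_floor, n)
  }
  adm <- report[report$min_cluster_size > floor_n, , drop = FALSE]
  if (nrow(adm) == 0) {
    stop(sprintf("no admissible configuration: every candidate has a cluster of size <= %d",
                 floor_n), call. = FALSE)
  }
  # canonical row order so the vote cannot depend on input ordering
  adm <- adm[order(adm$method, adm$k), , drop = FALSE]
  key <- paste(adm$method, adm$k, sep = "_")
  winners <- c(
    silhouette = key[which.max(adm$silhouette)],
    calinski_harabasz = key[which.max(adm$calinski_harabasz)],
    davies_bouldin = key[which.min(adm$davies_bouldin)])
  tally <- sort(table(winners), decreasing = TRUE)
  if (max(tally) >= 2) {
    chosen <- names(tally)[1]
  } else if (!is.null(prefer_k)) {
    cand <- adm[adm$k == prefer_k, , drop = FALSE]
    stop_if_not(nrow(cand) > 0, "prefer_k = %d has no admissible configuration", prefer_k)
    chosen <- with(cand, paste(method, k, sep = "_"))[which.max(cand$silhouette)]
  } else {
    stop(paste0("no majority among validity indices (three-way split): ",
                paste(names(winners), winners, sep = " -> ", collapse = "; "),
                "; set prefer_k to break the tie"), call. = FALSE)
  }
  parts <- strsplit(chosen, "_(?=[0-9]+$)", perl = TRUE)[[1]]
  list(method = parts[1], k = as.integer(parts[2]),
       winners = winners, tally = tally,
       admissible = adm,
       labels = attr(report, "labels")[[chosen]])
}
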