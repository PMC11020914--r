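#' Build a phenotypic disease network (PDN)
#'
#' Nodes are the diseases with nonzero prevalence in the patient subset;
#' an edge joins two diseases when the fraction of subset patients carrying
#' both — the co-occurrence prevalence, the edge weight — is at least
#' `edge_threshold` (pairs strictly below the threshold are discarded, so a
#' weight exactly at the threshold is retained). The denominator is always
#' the subset's own patient count: pass a cluster's patients for per-cluster
#' networks or the full cohort for the global one.
#'
#' @param flags binary patients x diseases table (data frame or matrix).
#' @param edge_threshold minimum co-occurrence prevalence (default 0.02).
#' @return an object of class `disease_network`: list with `nodes`
#'   (disease, prevalence, degree), `edges` (from, to, weight), `n_patients`
#'   and the `igraph` graph.
#' @export
build_pdn <- function(flags, edge_threshold = 0.02) {
  X <- as.matrix(flags)
  stop_if_not(nrow(X) > 0, "empty patient subset")
  stop_if_not(all(X %in% c(0, 1)), "comorbidity flags must be 0/1")
  n <- nrow(X)
  prev <- colMeans(X)
  keep <- prev > 0
  X <- X[, keep, drop = FALSE]
  prev <- prev[keep]
  d <- ncol(X)

  W <- crossprod(X) / n          # co-occurrence prevalence for every pair
  edges <- data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (d >= 2) {
    pairs <- which(upper.tri(W) & W >= edge_threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      edges <- data.frame(from = colnames(X)[pairs[, 1]],
                          to = colnames(X)[pairs[, 2]],
                          weight = W[pairs],
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = colnames(X), prevalence = prev))
  nodes <- data.frame(disease = colnames(X), prevalence = as.numeric(prev),
                      degree = as.integer(igraph::degree(g)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n_patients = n,
                 edge_threshold = edge_threshold, graph = g),
            class = "disease_network")
}

#' Graph metrics of a disease network
#'
#' `average_degree()` is `2 |E| / |V|` — the mean number of other diseases
#' each disease is connected to (10 for a complete graph on 11 nodes).
#' `average_clustering()` is the mean unweighted local clustering
#' coefficient: for each disease, the fraction of its neighbour pairs that
#' are themselves connected, with nodes of fewer than two neighbours
#' contributing 0; it is 1 exactly when every neighbourhood is a clique, as
#' in a complete graph.
#'
#' @param network a `disease_network`.
#' @return a single nonnegative number.
#' @export
average_degree <- function(network) {
  stop_if_not(inherits(network, "disease_network"), "not a disease_network")
  nv <- nrow(network$nodes)
  stop_if_not(nv > 0, "network has no nodes")
  2 * nrow(network$edges) / nv
}

#' @rdname average_degree
#' @export
average_clustering <- function(network) {
  stop_if_not(inherits(network, "disease_network"), "not a disease_network")
  nv <- nrow(network$nodes)
  stop_if_not(nv > 0, "network has no nodes")
  cc <- igraph::transitivity(network$graph, type = "local", isolates = "zero")
  mean(cc)
}

#' Export / import a disease network as plain files
#'
#' Writes a GraphML file (node attributes: prevalence, degree; edge
#' attribute: weight) for downstream visualization, plus a nodes CSV and a
#' weighted edge-list CSV which round-trip losslessly through
#' [read_network()].
#'
#' @param network a `disease_network`.
#' @param path basename for output files; `<path>.graphml`,
#'   `<path>_nodes.csv` and `<path>_edges.csv` are written.
#' @return the written paths, invisibly.
#' @export
export_network <- function(network, path) {
  stop_if_not(inherits(network, "disease_network"), "not a disease_network")
  dir <- dirname(path)
  stop_if_not(dir.exists(dir), "directory '%s' does not exist", dir)
  p_graphml <- paste0(path, ".graphml")
  p_nodes <- paste0(path, "_nodes.csv")
  p_edges <- paste0(path, "_edges.csv")
  g <- network$graph
  igraph::V(g)$degree <- network$nodes$degree
  igraph::write_graph(g, p_graphml, format = "graphml")
  meta <- data.frame(disease = network$nodes$disease,
                     prevalence = format(network$nodes$prevalence, digits = 17),
                     degree = network$nodes$degree,
                     n_patients = network$n_patients,
                     edge_threshold = format(network$edge_threshold, digits = 17),
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, p_nodes, row.names = FALSE)
  ed <- network$edges
  ed$weight <- format(ed$weight, digits = 17)
  utils::write.csv(ed, p_edges, row.names = FALSE)
  invisible(c(graphml = p_graphml, nodes = p_nodes, edges = p_edges))
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  nodes <- utils::read.csv(paste0(path, "_nodes.csv"), stringsAsFactors = FALSE)
  edges <- utils::read.csv(paste0(path, "_edges.csv"), stringsAsFactors = FALSE)
  edges$weight <- as.numeric(edges$weight)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$disease, prevalence = nodes$prevalence))
  structure(list(nodes = data.frame(disease = nodes$disease,
                                    prevalence = as.numeric(nodes$prevalence),
                                    degree = as.integer(nodes$degree),
                                    stringsAsFactors = FALSE),
                 edges = edges[, c("from", "to", "weight")],
                 n_patients = nodes$n_patients[1],
                 edge_threshold = as.numeric(nodes$edge_threshold[1]),
                 graph = g),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network> %d nodes, %d edges (threshold %.3g, %d patients)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_threshold, x$n_patients))
  invisible(x)
}
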