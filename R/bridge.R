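#' Bridge centrality indices
#'
#' Quantify how strongly each symptom connects to the *other* disorder's
#' cluster. Distances between nodes are `1/|weight|` per edge (stronger
#' association = shorter path), shortest paths by Dijkstra.
#'
#' * **Bridge strength**: sum of absolute edge weights from the focal
#'   symptom to all symptoms outside its own cluster.
#' * **Bridge betweenness**: number of cross-cluster pairs (s, t), both
#'   different from the focal symptom and in different clusters from each
#'   other, whose shortest path passes through the focal symptom. With
#'   tied shortest paths a pair counts once if any of them passes.
#' * **Bridge closeness**: inverse of the summed shortest distances from
#'   the focal symptom to every symptom outside its cluster; 0 if any of
#'   them is unreachable.
#'
#' @param graph A `symptom_network` object.
#' @param partition Cluster membership per node: a `symptom_partition`,
#'   a membership vector, or a character vector of disorder labels. For
#'   the comorbidity question this is normally the configured disorder
#'   dichotomy, not the detected communities.
#' @param nodes Node indices (default all).
#' @name bridge_centrality
NULL

membership_vector <- function(graph, partition) {
  memb <- if (inherits(partition, "symptom_partition"))
    partition$membership
  else if (is.character(partition))
    match(partition, unique(partition))
  else as.integer(partition)
  stopifnot(length(memb) == length(graph$labels))
  memb
}

#' @rdname bridge_centrality
#' @return `bridge_strength`: numeric vector of summed absolute
#'   cross-cluster weights.
#' @export
bridge_strength <- function(graph, partition, nodes = seq_along(graph$labels)) {
  memb <- membership_vector(graph, partition)
  A <- abs(graph$weights)
  vapply(nodes, function(v) sum(A[v, memb != memb[v]]), numeric(1))
}

# Dijkstra distances on 1/|w| edge lengths, via igraph
distance_matrix <- function(graph) {
  g <- as_igraph_abs(graph)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' @rdname bridge_centrality
#' @return `bridge_betweenness`: integer count of cross-cluster shortest
#'   paths through each node.
#' @export
bridge_betweenness <- function(graph, partition,
                               nodes = seq_along(graph$labels)) {
  memb <- membership_vector(graph, partition)
  p <- length(graph$labels)
  g <- as_igraph_abs(graph)
  len <- 1 / igraph::E(g)$weight
  counts <- integer(p)
  pairs <- which(outer(memb, memb, "!=") & upper.tri(diag(p)), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    s <- pairs[k, 1]; t <- pairs[k, 2]
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = t, weights = len))
    if (length(sp$res) == 0) next
    interior <- unique(unlist(lapply(sp$res, function(pp) {
      v <- as.integer(pp)
      if (length(v) > 2) v[-c(1, length(v))] else integer(0)
    })))
    counts[interior] <- counts[interior] + 1L
  }
  counts[nodes]
}

#' @rdname bridge_centrality
#' @return `bridge_closeness`: numeric vector, inverse summed distance to
#'   the other cluster(s).
#' @export
bridge_closeness <- function(graph, partition,
                             nodes = seq_along(graph$labels)) {
  memb <- membership_vector(graph, partition)
  D <- distance_matrix(graph)
  vapply(nodes, function(v) {
    d <- D[v, memb != memb[v]]
    if (any(!is.finite(d)) || length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
}

#' Bridge centrality table
#'
#' All three bridge indices per symptom, optionally with endorsement
#' rates, in the layout of a published symptom table.
#'
#' @inheritParams bridge_centrality
#' @param endorsement Optional endorsement rates (proportions) per node.
#' @return Data frame of class `bridge_table`: `label`, optional
#'   `endorsement_pct`, `bridge_strength`, `bridge_betweenness`,
#'   `bridge_closeness`.
#' @export
bridge_table <- function(graph, partition, endorsement = NULL) {
  out <- data.frame(
    label = graph$labels,
    bridge_strength = bridge_strength(graph, partition),
    bridge_betweenness = bridge_betweenness(graph, partition),
    bridge_closeness = bridge_closeness(graph, partition),
    stringsAsFactors = FALSE
  )
  if (!is.null(endorsement)) {
    out <- cbind(out[1], endorsement_pct = round_half_up(100 * endorsement, 1),
                 out[-1])
  }
  class(out) <- c("bridge_table", "data.frame")
  out
}
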