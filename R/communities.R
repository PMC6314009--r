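#' Walktrap community detection on a symptom network
#'
#' Short random walks on the absolute edge weights; nodes with similar
#' walk profiles are merged agglomeratively and the dendrogram is cut at
#' maximal modularity. Edge signs do not enter (random walks need
#' nonnegative weights); an edgeless graph returns singleton communities
#' with a warning.
#'
#' @param graph A `symptom_network` object.
#' @param steps Random-walk length (default 4, the reference
#'   implementation's default).
#' @return Object of class `symptom_partition`: `membership` (named,
#'   1-based contiguous ids), `n_communities`, `modularity`, `merges`
#'   (the dendrogram merge matrix, `NULL` for the edgeless case).
#' @export
walktrap_communities <- function(graph, steps = 4) {
  stopifnot(inherits(graph, "symptom_network"))
  p <- length(graph$labels)
  if (p < 1) stop("empty graph")
  if (all(graph$weights == 0)) {
    warning("graph has no edges; every node is its own community")
    return(new_partition(setNames(seq_len(p), graph$labels), 0, NULL))
  }
  g <- as_igraph_abs(graph)
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = steps)
  memb <- as.integer(igraph::membership(wt))
  memb <- match(memb, unique(memb))  # contiguous ids in first-seen order
  new_partition(setNames(memb, graph$labels),
                modularity_score(graph, memb),
                igraph::merges(wt))
}

new_partition <- function(membership, modularity, merges) {
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 modularity = modularity, merges = merges),
            class = "symptom_partition")
}

#' @export
print.symptom_partition <- function(x, ...) {
  cat("symptom_partition:", x$n_communities, "communities, modularity",
      sprintf("%.3f", x$modularity), "\n")
  invisible(x)
}

#' Newman modularity of a partition on absolute weights
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with `e_c` the total absolute
#' weight inside community `c`, `d_c` the summed absolute weighted
#' degrees, and `m` the total absolute edge weight.
#'
#' @param graph A `symptom_network` object.
#' @param partition A `symptom_partition` or a membership vector.
#' @return Modularity score.
#' @export
modularity_score <- function(graph, partition) {
  stopifnot(inherits(graph, "symptom_network"))
  memb <- if (inherits(partition, "symptom_partition"))
    partition$membership else partition
  stopifnot(length(memb) == length(graph$labels))
  A <- abs(graph$weights)
  m <- sum(A) / 2
  if (m <= 0) stop("modularity undefined: total edge weight is zero")
  deg <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    in_c <- memb == c
    e_c <- sum(A[in_c, in_c]) / 2
    d_c <- sum(deg[in_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Write a partition as JSON
#' @param partition A `symptom_partition`.
#' @param path Output path.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(list(
    membership = as.list(partition$membership),
    n_communities = partition$n_communities,
    modularity = partition$modularity,
    merges = partition$merges
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
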