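# Independent oracles and small fixture builders. Everything here is
# deliberately brute-force and shares no code with the package internals.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- function(x) sum(choose(x, 2))
  e <- s(rowSums(tab)) * s(colSums(tab)) / choose(n, 2)
  denom <- (s(rowSums(tab)) + s(colSums(tab))) / 2 - e
  if (denom == 0) return(1)
  (s(tab) - e) / denom
}

# random symmetric weight matrix (possible negative weights, ~60% density)
random_weights <- function(p, seed, density = 0.6, signed = TRUE) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < density) {
      w <- runif(1, 0.2, 1.5) * if (signed && runif(1) < 0.3) -1 else 1
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

make_net <- function(W, labels = paste0("V", seq_len(nrow(W)))) {
  symptom_network(W, labels = labels)
}

# brute-force bridge strength: double loop
oracle_bridge_strength <- function(W, memb, v) {
  s <- 0
  for (u in seq_len(nrow(W))) {
    if (memb[u] != memb[v]) s <- s + abs(W[v, u])
  }
  s
}

# all simple paths between s and t by DFS; returns list of vertex vectors
all_simple_paths_dfs <- function(W, s, t) {
  p <- nrow(W)
  out <- list()
  walk <- function(path, visited) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (u in seq_len(p)) {
      if (W[v, u] != 0 && !visited[u]) {
        visited[u] <- TRUE
        walk(c(path, u), visited)
        visited[u] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, p); vis[s] <- TRUE
  walk(s, vis)
  out
}

path_length <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / abs(W[cbind(path[-length(path)], path[-1])]))
}

# exhaustive-enumeration oracles for bridge betweenness and closeness
oracle_bridge_indices <- function(W, memb) {
  p <- nrow(W)
  betw <- integer(p)
  dist <- matrix(Inf, p, p); diag(dist) <- 0
  shortest_sets <- list()
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    paths <- all_simple_paths_dfs(W, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(pp) path_length(W, pp), numeric(1))
    dmin <- min(lens)
    dist[s, t] <- dist[t, s] <- dmin
    if (memb[s] != memb[t]) {
      sh <- paths[abs(lens - dmin) < 1e-9]
      interior <- unique(unlist(lapply(sh, function(pp) {
        if (length(pp) > 2) pp[-c(1, length(pp))] else integer(0)
      })))
      betw[interior] <- betw[interior] + 1L
    }
  }
  clo <- vapply(seq_len(p), function(v) {
    d <- dist[v, memb != memb[v]]
    if (length(d) == 0 || any(!is.finite(d))) 0 else 1 / sum(d)
  }, numeric(1))
  list(betweenness = betw, closeness = clo)
}

# small fast generator config for pipeline-level tests
small_config <- function(seed = 1L, ...) {
  cohort_config(
    n = 400, cluster_sizes = c(4, 3),
    target_endorsement_rates = c(0.2, 0.35, 0.45, 0.15, 0.3, 0.4, 0.25),
    n_bridge_edges = 1, seed = seed, ...
  )
}
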