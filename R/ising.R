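#' Ising model parameters on the {0,1} / log-odds scale
#'
#' The model places probability proportional to
#' `exp(sum_i tau_i x_i + sum_{i<j} omega_ij x_i x_j)` on each binary
#' state `x`. `tau` is the node parameter (autonomous log-odds preference
#' for 1); `omega` the symmetric interaction matrix with zero diagonal.
#'
#' @param tau Numeric vector of node parameters.
#' @param omega Symmetric numeric matrix with zero diagonal.
#' @param labels Optional node labels.
#' @return Object of class `ising_params`.
#' @export
ising_params <- function(tau, omega, labels = NULL) {
  tau <- as.numeric(tau)
  omega <- as.matrix(omega)
  p <- length(tau)
  if (!all(dim(omega) == c(p, p))) stop("omega must be p x p")
  if (max(abs(omega - t(omega))) > 1e-12) stop("omega must be symmetric")
  if (any(diag(omega) != 0)) stop("omega must have zero diagonal")
  omega <- (omega + t(omega)) / 2
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(omega) <- list(labels, labels)
  structure(list(tau = setNames(tau, labels), omega = omega, p = p,
                 labels = labels),
            class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat("ising_params:", x$p, "nodes,",
      sum(x$omega[upper.tri(x$omega)] != 0), "nonzero couplings\n")
  invisible(x)
}

#' Exact probability mass function over all 2^p states
#'
#' States are indexed 0..2^p-1; bit `i-1` of the index is node `i`
#' (`state_matrix()` decodes). Feasible up to p = 21 (2^21 states).
#'
#' @param params An [ising_params()] object.
#' @return Numeric vector of length `2^p` summing to 1.
#' @export
ising_pmf <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  if (params$p > 21) {
    stop("p > 21: exact enumeration infeasible, use ising_sample(method = \"gibbs\")")
  }
  cpp_ising_pmf(params$tau, params$omega)
}

#' Exact marginal endorsement probabilities by enumeration
#' @inheritParams ising_pmf
#' @return Numeric vector of `P(x_i = 1)`, one per node.
#' @export
ising_marginals <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  if (params$p > 21) stop("p > 21: exact enumeration infeasible")
  setNames(cpp_ising_marginals(params$tau, params$omega), params$labels)
}

#' Decode state indices into a binary matrix
#' @param idx Zero-based state indices.
#' @param p Number of nodes.
#' @return Integer matrix, one row per index, columns in node order.
#' @export
state_matrix <- function(idx, p) {
  out <- matrix(0L, length(idx), p)
  for (j in seq_len(p)) out[, j] <- bitwAnd(idx %/% 2^(j - 1), 1L)
  out
}

#' Conditional logit of one node given the rest
#'
#' `P(x_i = 1 | x_-i) = logistic(tau_i + sum_{j != i} omega_ij x_j)`:
#' the exact conditional each nodewise logistic regression targets.
#'
#' @inheritParams ising_pmf
#' @param node Node index.
#' @return List with `intercept` (`tau_i`) and `coefficients` (row `i`
#'   of omega without the diagonal, named by the other nodes).
#' @export
ising_conditional <- function(params, node) {
  stopifnot(inherits(params, "ising_params"),
            node >= 1, node <= params$p)
  co <- params$omega[node, -node]
  list(intercept = unname(params$tau[node]), coefficients = co)
}

#' Sample binary data from an Ising model
#'
#' `method = "exact"` draws i.i.d. states by inverse-CDF from the
#' enumerated pmf (p <= 20); `"gibbs"` runs a single-site Gibbs sampler
#' (any p) with burn-in and thinning; `"auto"` picks exact when feasible.
#' Deterministic under `seed`.
#'
#' @inheritParams ising_pmf
#' @param n Number of respondents to draw.
#' @param seed Integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @param method One of `"auto"`, `"exact"`, `"gibbs"`.
#' @param burnin,thin Gibbs burn-in sweeps and thinning interval.
#' @param disorder Optional disorder labels attached to the output.
#' @return A [symptom_data()] object.
#' @export
ising_sample <- function(params, n, seed = NULL,
                         method = c("auto", "exact", "gibbs"),
                         burnin = 1000, thin = 10, disorder = NULL) {
  stopifnot(inherits(params, "ising_params"), n >= 1)
  method <- match.arg(method)
  if (method == "auto") method <- if (params$p <= 20) "exact" else "gibbs"
  if (method == "exact" && params$p > 20) {
    stop("exact sampling limited to p <= 20; use method = \"gibbs\"")
  }
  if (method == "gibbs" && (burnin < 1 || thin < 1)) {
    stop("gibbs sampling requires burnin >= 1 and thin >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- if (method == "exact") {
    pmf <- cpp_ising_pmf(params$tau, params$omega)
    idx <- sample.int(length(pmf), n, replace = TRUE, prob = pmf) - 1L
    state_matrix(idx, params$p)
  } else {
    cpp_ising_gibbs(params$tau, params$omega, as.integer(n),
                    as.integer(burnin), as.integer(thin))
  }
  symptom_data(x, labels = params$labels, disorder = disorder)
}

#' Calibrate node thresholds to target endorsement rates
#'
#' Holding the couplings fixed, each `tau_i` is moved by exact monotone
#' coordinate updates (the closed-form limit of a per-node bisection: the
#' node's marginal is logistic in its own threshold) until every marginal
#' from exact enumeration is within `tol` of its target.
#'
#' @inheritParams ising_pmf
#' @param targets Marginal endorsement rates in (0, 1), one per node.
#' @param tol Convergence tolerance on each marginal (default 0.005).
#' @param max_rounds Maximum rounds over the nodes (default 200).
#' @return An [ising_params()] object with calibrated `tau`.
#' @export
calibrate_thresholds <- function(params, targets, tol = 0.005,
                                 max_rounds = 200) {
  stopifnot(inherits(params, "ising_params"),
            length(targets) == params$p,
            all(targets > 0 & targets < 1))
  res <- cpp_calibrate_tau(params$tau, params$omega, as.numeric(targets),
                           tol, as.integer(max_rounds))
  if (!res$converged) {
    worst_node <- params$labels[which.max(abs(res$marginals - targets))]
    stop("threshold calibration did not converge in ", max_rounds,
         " rounds; worst node ", worst_node,
         sprintf(" (off by %.4f)", res$worst))
  }
  ising_params(res$tau, params$omega, params$labels)
}

#' Configuration for the study-like two-disorder cohort generator
#'
#' Defaults describe a two-disorder symptom cohort: 11 alcohol symptoms
#' (`A1..A11`) and 10 cannabis symptoms (`C1..C10`), n = 1559
#' respondents, endorsement rates spanning roughly 5-50%, dense positive
#' within-disorder couplings and a handful of weaker between-disorder
#' ("bridge") couplings with a unique strongest bridge.
#'
#' @param n Cohort size.
#' @param cluster_sizes Sizes of the two disorder clusters.
#' @param within_edge_probability Probability that a within-cluster node
#'   pair is coupled.
#' @param within_weight_range Range of (uniform) within-cluster coupling
#'   weights, log-odds scale.
#' @param n_bridge_edges Number of between-cluster couplings.
#' @param bridge_weight Weight of the strongest bridge edge; the
#'   remaining bridges scale down a fixed descending profile
#'   (`1, 0.7, 0.4, ...`) so a unique strongest bridge exists.
#' @param target_endorsement_rates Length-`sum(cluster_sizes)` marginal
#'   rates in (0, 1).
#' @param seed Integer seed governing structure and weights.
#' @param include_zero_variance_column If `TRUE`, the last cannabis
#'   column of any generated sample is forced to 1 for everyone, to
#'   exercise the zero-variance exclusion rule.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 1559,
                          cluster_sizes = c(11, 10),
                          within_edge_probability = 0.6,
                          within_weight_range = c(0.5, 1.5),
                          n_bridge_edges = 3,
                          bridge_weight = 1.5,
                          target_endorsement_rates = default_endorsement_rates(),
                          seed = 1L,
                          include_zero_variance_column = FALSE) {
  p <- sum(cluster_sizes)
  stopifnot(length(cluster_sizes) == 2, p >= 2,
            length(target_endorsement_rates) == p,
            all(target_endorsement_rates > 0 & target_endorsement_rates < 1),
            n_bridge_edges >= 0)
  structure(list(
    n = n, cluster_sizes = cluster_sizes,
    within_edge_probability = within_edge_probability,
    within_weight_range = within_weight_range,
    n_bridge_edges = n_bridge_edges, bridge_weight = bridge_weight,
    target_endorsement_rates = target_endorsement_rates,
    seed = as.integer(seed),
    include_zero_variance_column = include_zero_variance_column
  ), class = "cohort_config")
}

#' Default endorsement-rate profile for the 21-symptom cohort
#'
#' Eleven alcohol and ten cannabis rates spanning ~5% to ~49%, ordered as
#' `A1..A11, C1..C10`; the mix of common (tolerance-type) and rare
#' (withdrawal-type) symptoms typical of young-adult community samples.
#'
#' @return Numeric vector of length 21.
#' @export
default_endorsement_rates <- function() {
  c(0.209, 0.454, 0.081, 0.342, 0.069, 0.430, 0.058, 0.266, 0.050, 0.054,
    0.060,
    0.486, 0.374, 0.463, 0.203, 0.360, 0.166, 0.293, 0.393, 0.184, 0.124)
}

#' Generate study-like ground-truth Ising parameters
#'
#' Draws a two-cluster coupling structure per the configuration (dense
#' within-cluster, `n_bridge_edges` between-cluster couplings at seeded
#' random node pairs with a descending weight profile), then calibrates
#' thresholds so each node's exact marginal matches its target rate.
#'
#' @param config A [cohort_config()] object.
#' @return List of class `cohort_truth`: `params` ([ising_params()]),
#'   `edges` (data frame `i, j, weight, type`), `disorder` labels,
#'   `config`.
#' @export
study_parameters <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sz <- config$cluster_sizes
  p <- sum(sz)
  labels <- c(paste0("A", seq_len(sz[1])), paste0("C", seq_len(sz[2])))
  disorder <- rep(c("alcohol", "cannabis"), sz)
  omega <- matrix(0, p, p)
  edges <- list()
  for (cl in 1:2) {
    idx <- if (cl == 1) seq_len(sz[1]) else sz[1] + seq_len(sz[2])
    pairs <- t(combn(idx, 2))
    on <- runif(nrow(pairs)) < config$within_edge_probability
    w <- runif(nrow(pairs), config$within_weight_range[1],
               config$within_weight_range[2])
    for (k in which(on)) {
      omega[pairs[k, 1], pairs[k, 2]] <- w[k]
      omega[pairs[k, 2], pairs[k, 1]] <- w[k]
    }
    edges[[cl]] <- data.frame(i = pairs[on, 1], j = pairs[on, 2],
                              weight = w[on], type = "within")
  }
  nb <- config$n_bridge_edges
  if (nb > 0) {
    cross <- expand.grid(i = seq_len(sz[1]), j = sz[1] + seq_len(sz[2]))
    pick <- cross[sample.int(nrow(cross), nb), , drop = FALSE]
    bw <- config$bridge_weight *
      seq(1, by = -0.3, length.out = nb)
    bw <- pmax(bw, 0.1 * config$bridge_weight)
    for (k in seq_len(nb)) {
      omega[pick$i[k], pick$j[k]] <- bw[k]
      omega[pick$j[k], pick$i[k]] <- bw[k]
    }
    edges[[3]] <- data.frame(i = pick$i, j = pick$j, weight = bw,
                             type = "bridge")
  }
  edge_df <- do.call(rbind, edges)
  rownames(edge_df) <- NULL
  params <- ising_params(rep(0, p), omega, labels)
  params <- calibrate_thresholds(params, config$target_endorsement_rates)
  structure(list(params = params, edges = edge_df, disorder = disorder,
                 config = config),
            class = "cohort_truth")
}

#' Simulate a study-like cohort with known ground truth
#'
#' @inheritParams study_parameters
#' @param method Sampling method passed to [ising_sample()]; the default
#'   uses Gibbs at p = 21 (exact inverse-CDF tables stop at p = 20).
#' @return List: `data` ([symptom_data()]), `truth` ([study_parameters()]
#'   output).
#' @export
simulate_cohort <- function(config = cohort_config(), method = "auto") {
  truth <- study_parameters(config)
  # derived stream: structure and sampling decouple, both seeded
  dat <- ising_sample(truth$params, config$n,
                      seed = config$seed + 1000L, method = method,
                      disorder = truth$disorder)
  if (config$include_zero_variance_column) {
    x <- dat$x
    x[, ncol(x)] <- 1L
    dat <- symptom_data(x, labels = dat$labels, disorder = dat$disorder)
  }
  list(data = dat, truth = truth)
}

#' Serialize cohort ground truth as JSON
#' @param truth A `cohort_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  p <- truth$params$p
  lower <- truth$params$omega[lower.tri(truth$params$omega)]
  jsonlite::write_json(list(
    labels = truth$params$labels,
    disorder = truth$disorder,
    tau = unname(truth$params$tau),
    omega_lower_triangle = lower,
    edges = truth$edges,
    seed = truth$config$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
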