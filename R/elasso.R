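#' Configuration for eLasso network estimation
#'
#' @param gamma EBIC hyperparameter (>= 0). Default 0.25, the convention
#'   of the reference binary-network estimator.
#' @param n_lambda Size of the penalty grid (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the
#'   data-derived `lambda_max` (default 0.01).
#' @param rule Symmetrization rule, `"AND"` (edge kept only when both
#'   nodewise regressions select it; default) or `"OR"` (kept when either
#'   does, the unselected coefficient counting as 0 in the mean).
#' @param tol Coordinate-descent convergence tolerance.
#' @param maxit Maximum coordinate-descent cycles per penalty value.
#' @return List of class `estimation_config`.
#' @export
estimation_config <- function(gamma = 0.25, n_lambda = 100,
                              lambda_min_ratio = 0.01,
                              rule = c("AND", "OR"),
                              tol = 1e-7, maxit = 2000) {
  rule <- match.arg(rule)
  stopifnot(gamma >= 0, n_lambda >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, rule = rule,
                 tol = tol, maxit = maxit),
            class = "estimation_config")
}

# largest penalty with all coefficients zero (KKT at full shrinkage),
# weighted-covariance form
lambda_max <- function(y, X, weights = rep(1, length(y))) {
  W <- sum(weights)
  yc <- y - sum(weights * y) / W
  xc <- sweep(X, 2, colSums(weights * X) / W)
  max(abs(colSums(weights * xc * yc))) / W
}

#' L1-penalized logistic regression path
#'
#' Minimizes the weighted mean negative log-likelihood plus
#' `lambda * sum(|beta|)` (intercept unpenalized) by cyclic coordinate
#' descent on the iteratively reweighted quadratic approximation, with
#' warm starts along a descending penalty grid.
#'
#' @param y Binary response vector.
#' @param X Design matrix (binary columns in the Ising use; no constant
#'   columns).
#' @param lambdas Descending penalty values; defaults to `n_lambda`
#'   log-spaced values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`. May include 0 (unpenalized MLE).
#' @param weights Optional nonnegative observation weights.
#' @param config An [estimation_config()].
#' @return List of class `lasso_path`: `lambdas`, `beta0`, `beta`
#'   (coefficients x penalties), `loglik` (weighted, at the fit),
#'   `iterations`, `converged`, `diverged`.
#' @export
logistic_lasso_path <- function(y, X, lambdas = NULL,
                                weights = rep(1, length(y)),
                                config = estimation_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(weights) == length(y),
            all(weights >= 0))
  sd0 <- apply(X[weights > 0, , drop = FALSE], 2, function(c) max(c) - min(c))
  if (any(sd0 == 0)) stop("constant predictor column(s): ",
                          paste(which(sd0 == 0), collapse = ", "))
  if (is.null(lambdas)) {
    lmax <- lambda_max(y, X, weights)
    lambdas <- exp(seq(log(lmax), log(config$lambda_min_ratio * lmax),
                       length.out = config$n_lambda))
  }
  fit <- cpp_logistic_lasso_path(X, y, as.numeric(weights),
                                 as.numeric(lambdas),
                                 config$tol, as.integer(config$maxit))
  if (any(!fit$converged & !fit$diverged)) {
    bad <- which(!fit$converged & !fit$diverged)[1]
    stop(sprintf(
      "coordinate descent did not converge at lambda = %.6g (%d cycles)",
      lambdas[bad], fit$iterations[bad]))
  }
  structure(list(lambdas = lambdas, beta0 = fit$beta0, beta = fit$beta,
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, diverged = fit$diverged),
            class = "lasso_path")
}

#' Extended Bayesian information criterion
#'
#' `-2 loglik + k log(n) + 2 gamma k log(q)`, where `k` is the number of
#' nonzero coefficients and `q` the number of candidate predictors.
#' `gamma = 0` recovers the classical BIC.
#'
#' @param loglik Maximized log-likelihood of the model.
#' @param k_nonzero Number of selected (nonzero) coefficients.
#' @param n Sample size.
#' @param n_candidates Number of candidate predictors.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return EBIC score (smaller is better).
#' @export
ebic <- function(loglik, k_nonzero, n, n_candidates, gamma) {
  stopifnot(n >= 1, n_candidates >= 1, gamma >= 0)
  -2 * loglik + k_nonzero * log(n) + 2 * gamma * k_nonzero * log(n_candidates)
}

#' Fit one node's penalized regression and select its model by EBIC
#'
#' Regresses the node on all other symptoms over the penalty path and
#' returns the fit minimizing the EBIC (ties resolved toward the larger
#' penalty, i.e. the sparser model). Perfect separation — a diverging
#' fit along the path — is flagged with a warning and the selection is
#' restricted to the stable part of the path.
#'
#' @param data A [symptom_data()] object with no zero-variance columns.
#' @param node Node index (column of `data`).
#' @param config An [estimation_config()].
#' @param weights Optional observation weights.
#' @return List: `node`, `intercept`, `coefficients` (named over the
#'   other nodes; unselected entries exactly 0), `lambda`, `ebic`,
#'   `path_ebic`, `path` (the full [logistic_lasso_path()]), `separation`.
#' @export
fit_node <- function(data, node, config = estimation_config(),
                     weights = NULL) {
  stopifnot(inherits(data, "symptom_data"))
  y <- data$x[, node]
  X <- data$x[, -node, drop = FALSE]
  if (is.null(weights)) weights <- rep(1, data$n)
  path <- logistic_lasso_path(y, X, weights = weights, config = config)
  usable <- !path$diverged
  separation <- any(path$diverged)
  if (separation) {
    # keep the stable head of the path only
    first_bad <- which(path$diverged)[1]
    usable <- seq_along(path$lambdas) < first_bad
    warning("possible perfect separation for node ", data$labels[node],
            "; selection restricted to the stable part of the path")
    if (!any(usable)) stop("no stable penalty value for node ",
                           data$labels[node])
  }
  k <- colSums(path$beta != 0)
  scores <- ebic(path$loglik, k, sum(weights), ncol(X), config$gamma)
  scores[!usable] <- Inf
  best <- which(scores == min(scores))[1]  # path descends: first = largest lambda
  co <- setNames(path$beta[, best], data$labels[-node])
  list(node = node, label = data$labels[node],
       intercept = path$beta0[best], coefficients = co,
       lambda = path$lambdas[best], ebic = scores[best],
       path_ebic = scores, path = path, separation = separation)
}

#' Estimate a symptom network (eLasso)
#'
#' Runs [fit_node()] for every symptom and symmetrizes the directed
#' coefficients into an undirected weighted network. Under the AND rule
#' an edge is present only if both regressions select it, with weight the
#' mean of the two coefficients; under OR, if either selects it, the
#' missing coefficient counting as 0 in the mean.
#'
#' @param data A [symptom_data()] object (prepared: no missing values,
#'   no zero-variance columns).
#' @param config An [estimation_config()].
#' @return Object of class `symptom_network`: `weights` (p x p symmetric,
#'   zero diagonal), `thresholds` (selected intercepts), `labels`,
#'   `disorder`, `beta` (the directed coefficient matrix, row = response
#'   node), `config`, `fits` (per-node selection metadata).
#' @export
estimate_network <- function(data, config = estimation_config()) {
  stopifnot(inherits(data, "symptom_data"))
  p <- data$p
  B <- matrix(0, p, p, dimnames = list(data$labels, data$labels))
  thresholds <- numeric(p)
  fits <- vector("list", p)
  for (i in seq_len(p)) {
    f <- fit_node(data, i, config)
    B[i, -i] <- f$coefficients
    thresholds[i] <- f$intercept
    fits[[i]] <- f[c("label", "lambda", "ebic", "separation")]
  }
  sel <- (B != 0)
  keep <- if (config$rule == "AND") sel & t(sel) else sel | t(sel)
  W <- (B + t(B)) / 2
  W[!keep] <- 0
  diag(W) <- 0
  structure(list(weights = W, thresholds = setNames(thresholds, data$labels),
                 labels = data$labels, disorder = data$disorder,
                 beta = B, config = config, fits = fits),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("symptom_network:", length(x$labels), "nodes,", ne, "edges (",
      x$config$rule, "rule, gamma =", x$config$gamma, ")\n")
  invisible(x)
}

#' Edge list of a symptom network
#' @param graph A `symptom_network` (or compatible) object.
#' @return Data frame `from, to, weight` over nonzero upper-triangle
#'   entries.
#' @export
network_edges <- function(graph) {
  W <- graph$weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(from = graph$labels[ut[, 1]], to = graph$labels[ut[, 2]],
             weight = W[ut], stringsAsFactors = FALSE)
}

#' Construct a symptom network from a weight matrix
#'
#' Useful for analysing externally estimated networks with the community,
#' bridge and reporting tools.
#'
#' @param weights Symmetric numeric matrix, zero diagonal.
#' @param labels Node labels.
#' @param disorder Optional disorder labels.
#' @param thresholds Optional node thresholds.
#' @return A `symptom_network` object.
#' @export
symptom_network <- function(weights, labels = colnames(weights),
                            disorder = NULL, thresholds = NULL) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (max(abs(weights - t(weights))) > 1e-12) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights,
                 thresholds = thresholds %||% setNames(rep(NA_real_, p), labels),
                 labels = labels, disorder = disorder,
                 beta = NULL, config = NULL, fits = NULL),
            class = "symptom_network")
}

# igraph view on absolute weights (walks and distances need nonnegative
# weights; the two negative edges a symptom network may carry enter by
# magnitude)
as_igraph_abs <- function(graph) {
  A <- abs(graph$weights)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
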