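#' Bootstrapped edge-weight accuracy
#'
#' Nonparametric case resampling: `B` resamples of respondents with
#' replacement, the full eLasso network re-estimated on each, and 95%
#' percentile confidence intervals formed per edge (over all node pairs;
#' an edge absent in a replicate contributes weight 0). A node losing all
#' variance in a resample has its edges recorded as 0 in that replicate;
#' a replicate with fewer than two varying columns is degenerate, and
#' more than `max_degenerate_share` degenerate replicates abort.
#'
#' @param data A [symptom_data()] object.
#' @param config An [estimation_config()].
#' @param B Number of bootstrap replicates (>= 2). Default 1000;
#'   200 is adequate for smoke tests.
#' @param seed Integer seed governing all resampling.
#' @param resample Optional hook `function(n, b)` returning the row
#'   indices of replicate `b` (testing aid; e.g. the identity).
#' @param max_degenerate_share Abort threshold (default 0.5).
#' @return Object of class `bootstrap_summary`: `edges` (data frame:
#'   `from, to, estimate, ci_low, ci_high`), `replicates` (B x n_pairs
#'   matrix of weights), `overlap` (logical matrix over the nonzero
#'   edges: do the two CIs overlap?), `overlap_share`, `B`, `seed`,
#'   `n_degenerate`, `network` (the point-estimate network).
#' @export
bootstrap_edges <- function(data, config = estimation_config(), B = 1000,
                            seed = NULL, resample = NULL,
                            max_degenerate_share = 0.5) {
  stopifnot(inherits(data, "symptom_data"), B >= 2)
  if (!is.null(seed)) set.seed(seed)
  p <- data$p
  # network on (a resample of) the rows: zero-variance nodes contribute
  # zero-weight edges; NULL when fewer than two columns retain variance
  guarded <- function(x) {
    rate <- colMeans(x)
    ok <- rate > 0 & rate < 1
    if (sum(ok) < 2L) return(NULL)
    sub <- symptom_data(x[, ok, drop = FALSE],
                        labels = data$labels[ok],
                        disorder = if (is.null(data$disorder)) NULL else
                          data$disorder[ok])
    W <- matrix(0, p, p)
    W[ok, ok] <- estimate_network(sub, config)$weights
    W
  }
  W0 <- guarded(data$x)
  point <- symptom_network(if (is.null(W0)) matrix(0, p, p) else W0,
                           labels = data$labels, disorder = data$disorder)
  ut <- which(upper.tri(point$weights), arr.ind = TRUE)
  n_pairs <- nrow(ut)
  reps <- matrix(0, B, n_pairs)
  n_degenerate <- 0L
  for (b in seq_len(B)) {
    idx <- if (is.null(resample)) {
      sample.int(data$n, data$n, replace = TRUE)
    } else resample(data$n, b)
    Wb <- guarded(data$x[idx, , drop = FALSE])
    if (is.null(Wb)) {
      n_degenerate <- n_degenerate + 1L
      next  # replicate recorded as all-zero weights
    }
    reps[b, ] <- Wb[upper.tri(Wb)]
  }
  if (n_degenerate > max_degenerate_share * B) {
    stop(n_degenerate, " of ", B,
         " bootstrap replicates were degenerate (no estimable network)")
  }
  ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  edges <- data.frame(
    from = data$labels[ut[, 1]], to = data$labels[ut[, 2]],
    estimate = point$weights[ut],
    ci_low = ci[1, ], ci_high = ci[2, ],
    stringsAsFactors = FALSE
  )
  nz <- which(edges$estimate != 0)
  overlap <- NULL
  overlap_share <- NA_real_
  if (length(nz) >= 2) {
    lo <- edges$ci_low[nz]; hi <- edges$ci_high[nz]
    overlap <- outer(lo, hi, function(a, b) a <= b) &
      t(outer(lo, hi, function(a, b) a <= b))
    dimnames(overlap) <- list(paste(edges$from[nz], edges$to[nz], sep = "--"),
                              paste(edges$from[nz], edges$to[nz], sep = "--"))
    ut2 <- upper.tri(overlap)
    overlap_share <- mean(overlap[ut2])
  }
  structure(list(edges = edges, replicates = reps, overlap = overlap,
                 overlap_share = overlap_share, B = B, seed = seed,
                 n_degenerate = n_degenerate, network = point),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  nz <- x$edges[x$edges$estimate != 0, ]
  cat("bootstrap_summary: B =", x$B, ",", nrow(nz), "edges;",
      sprintf("%.1f%%", 100 * x$overlap_share),
      "of edge-pair CIs overlap\n")
  invisible(x)
}

#' Write bootstrap CIs as CSV and the overlap summary as JSON
#' @param boot A `bootstrap_summary`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_bootstrap <- function(boot, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(boot$edges, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(B = boot$B,
                              n_degenerate = boot$n_degenerate,
                              overlap_share = boot$overlap_share),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(boot)
}
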