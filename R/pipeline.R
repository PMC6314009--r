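#' Between-disorder edge summary
#'
#' Counts the network's between-cluster edges by sign against the
#' disorder rosters and expresses the positive count as a percentage of
#' all possible between-cluster pairs (`n_alcohol x n_cannabis`),
#' rounded half-away-from-zero to one decimal.
#'
#' @param graph A `symptom_network` object.
#' @param disorder Disorder label per node (exactly two distinct values);
#'   defaults to the network's stored labels.
#' @param extra_roster Optional named counts to add to each disorder's
#'   roster size, for symptoms excluded from the network (e.g. dropped
#'   for zero variance) that still belong to the questionnaire roster the
#'   denominator should reflect.
#' @return List: `positive`, `negative`, `possible`, `percentage`.
#' @export
between_cluster_summary <- function(graph, disorder = graph$disorder,
                                    extra_roster = NULL) {
  if (is.null(disorder)) stop("disorder labels required")
  stopifnot(length(disorder) == length(graph$labels))
  lev <- unique(disorder)
  if (length(lev) != 2) {
    stop("exactly two disorders required, got: ",
         paste(lev, collapse = ", "))
  }
  sizes <- table(factor(disorder, levels = lev))
  if (!is.null(extra_roster)) {
    for (nm in names(extra_roster)) sizes[nm] <- sizes[nm] + extra_roster[[nm]]
  }
  possible <- as.integer(sizes[1]) * as.integer(sizes[2])
  W <- graph$weights
  between <- outer(disorder, disorder, "!=") & upper.tri(W)
  w <- W[between]
  positive <- sum(w > 0)
  negative <- sum(w < 0)
  list(positive = positive, negative = negative, possible = possible,
       percentage = round_half_up(100 * positive / possible, 1))
}

#' Write a network as labeled adjacency CSV, edge-list CSV and GraphML
#'
#' @param graph A `symptom_network`.
#' @param adjacency_path,edges_path,graphml_path,thresholds_path Output
#'   paths; any may be `NULL` to skip.
#' @export
write_network <- function(graph, adjacency_path = NULL, edges_path = NULL,
                          graphml_path = NULL, thresholds_path = NULL) {
  if (!is.null(adjacency_path)) {
    df <- data.frame(label = graph$labels, graph$weights,
                     check.names = FALSE)
    write.csv(df, adjacency_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(edges_path)) {
    write.csv(network_edges(graph), edges_path, row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_adjacency_matrix(graph$weights,
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(thresholds_path)) {
    jsonlite::write_json(as.list(graph$thresholds), thresholds_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(graph)
}

#' Pipeline configuration
#'
#' @param input Path to a respondent-by-symptom CSV, or `NULL` to
#'   generate synthetic data.
#' @param generator A [cohort_config()] used when `input` is `NULL`.
#' @param estimation An [estimation_config()].
#' @param walk_steps Walktrap walk length.
#' @param bootstrap_B Bootstrap replicates; `NULL` disables the
#'   bootstrap stage.
#' @param min_rows Minimum retained sample size for preparation.
#' @param count_excluded_in_roster If `TRUE` (default), symptoms dropped
#'   for zero variance still count in the between-disorder denominator
#'   (the full questionnaire rosters).
#' @param out_dir Output directory for artifacts (`NULL`: no files).
#' @param seed Master seed for stages not otherwise seeded.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = cohort_config(),
                            estimation = estimation_config(),
                            walk_steps = 4, bootstrap_B = NULL,
                            min_rows = 50,
                            count_excluded_in_roster = TRUE,
                            out_dir = NULL, seed = 1L) {
  structure(list(input = input, generator = generator,
                 estimation = estimation, walk_steps = walk_steps,
                 bootstrap_B = bootstrap_B, min_rows = min_rows,
                 count_excluded_in_roster = count_excluded_in_roster,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full symptom-network pipeline
#'
#' data preparation -> eLasso network -> walktrap communities -> bridge
#' centrality against the disorder dichotomy -> optional bootstrap ->
#' report. Each stage failure aborts with the stage named. The run is a
#' pure function of (input data or generator seed, configuration); the
#' report carries no timestamps so repeated runs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `report` (see below), `data`,
#'   `network`, `partition`, `bridge`, `bootstrap` (`NULL` when
#'   disabled), `prep_log`, `truth` (generator runs only). The report
#'   holds n/p used, drop counts, community count, between-disorder edge
#'   counts and percentage, top bridge symptoms per index, seeds, and
#'   artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  prep <- stage("data_prep", {
    if (!is.null(config$input)) {
      read_symptom_csv(config$input, min_rows = config$min_rows)
    } else {
      sim <- simulate_cohort(config$generator)
      truth <- sim$truth   # stage expr evaluates in this frame
      res <- prepare_symptoms(sim$data$x, labels = sim$data$labels,
                              disorder = sim$data$disorder,
                              min_rows = config$min_rows)
      res
    }
  })
  dat <- prep$data
  if (is.null(dat$disorder)) {
    stop("pipeline stage 'data_prep' failed: disorder labels could not ",
         "be inferred from the symptom labels", call. = FALSE)
  }
  net <- stage("estimate_network", estimate_network(dat, config$estimation))
  part <- stage("communities", walktrap_communities(net, config$walk_steps))
  br <- stage("bridge", bridge_table(net, dat$disorder,
                                     endorsement = colMeans(dat$x)))
  boot <- NULL
  if (!is.null(config$bootstrap_B)) {
    boot <- stage("bootstrap",
                  bootstrap_edges(dat, config$estimation,
                                  B = config$bootstrap_B,
                                  seed = config$seed + 2000L))
  }
  # roster accounting for excluded zero-variance symptoms
  extra <- NULL
  if (config$count_excluded_in_roster && nrow(prep$log$dropped_columns) > 0) {
    pre <- substr(prep$log$dropped_columns$label, 1, 1)
    dropped_dis <- ifelse(pre == "A", "alcohol", "cannabis")
    extra <- as.list(table(dropped_dis))
  }
  bc <- stage("report", between_cluster_summary(net, dat$disorder,
                                                extra_roster = extra))
  top3 <- function(v) dat$labels[order(-v)][1:min(3, length(v))]
  report <- list(
    n = dat$n, p = dat$p,
    dropped_rows = prep$log$n_dropped_rows,
    dropped_columns = prep$log$dropped_columns$label,
    n_communities = part$n_communities,
    modularity = part$modularity,
    n_edges = nrow(network_edges(net)),
    between = bc,
    top_bridge = list(
      strength = top3(br$bridge_strength),
      betweenness = top3(br$bridge_betweenness),
      closeness = top3(br$bridge_closeness)
    ),
    bootstrap = if (is.null(boot)) NULL else
      list(B = boot$B, overlap_share = boot$overlap_share),
    seeds = list(master = config$seed,
                 generator = if (is.null(config$input))
                   config$generator$seed else NULL),
    artifacts = character(0)
  )
  out <- structure(list(report = report, data = dat, network = net,
                        partition = part, bridge = br, bootstrap = boot,
                        prep_log = prep$log, truth = truth,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    out$report$artifacts <- write_pipeline_artifacts(out, config$out_dir)
  }
  out
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_symptom_csv(result$data, f("data.csv"))
  write_network(result$network, f("adjacency.csv"), f("edges.csv"),
                f("network.graphml"), f("thresholds.json"))
  write_partition_json(result$partition, f("partition.json"))
  write.csv(result$bridge, f("bridge.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(result$bootstrap)) {
    write_bootstrap(result$bootstrap, f("bootstrap.csv"),
                    f("bootstrap_overlap.json"))
  }
  if (!is.null(result$truth)) {
    write_ground_truth(result$truth, f("ground_truth.json"))
  }
  jsonlite::write_json(result$report, f("report.json"),
                       auto_unbox = TRUE, digits = NA)
  prep_log <- result$prep_log
  jsonlite::write_json(list(
    n_dropped_rows = prep_log$n_dropped_rows,
    dropped_columns = prep_log$dropped_columns,
    endorsement = as.list(prep_log$endorsement)
  ), f("prep_log.json"), auto_unbox = TRUE, digits = NA)
  basename(c(f("data.csv"), f("adjacency.csv"), f("edges.csv"),
             f("network.graphml"), f("thresholds.json"),
             f("partition.json"), f("bridge.csv"), f("report.json"),
             f("prep_log.json")))
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pipeline_result: n =", r$n, ", p =", r$p, "\n")
  cat("  communities:", r$n_communities,
      sprintf("(modularity %.3f)", r$modularity), "\n")
  cat("  edges:", r$n_edges, "total;", r$between$positive,
      "positive /", r$between$negative, "negative between disorders",
      sprintf("(%s%% of %d possible pairs)",
              format(r$between$percentage, nsmall = 1), r$between$possible),
      "\n")
  cat("  top bridge strength:", paste(r$top_bridge$strength,
                                      collapse = ", "), "\n")
  invisible(x)
}
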