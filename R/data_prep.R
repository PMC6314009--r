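#' Response scales for the screening item and the cannabis (CUDIT) items
#'
#' The simultaneous-use screening item is answered on a fixed six-point
#' frequency scale. The ten CUDIT items are ordinal; items 1 (use
#' frequency) and 2 (hours spent stoned) have their own four-point scales,
#' items 3-10 share a five-point frequency scale starting at "never".
#'
#' @format Character vectors of ordered category labels, lowest first.
#' @name response_scales
NULL

#' @rdname response_scales
#' @export
simultaneous_use_levels <- c(
  "never", "hardly ever", "seldom", "more or less half of the time",
  "often", "almost always"
)

#' @rdname response_scales
#' @export
cudit_scales <- c(
  list(
    c("less than a month", "monthly", "weekly", "daily or almost daily"),
    c("one or two h", "three or four h", "five or six h", "seven h or more")
  ),
  rep(list(c("never", "less than a month", "monthly", "weekly",
             "daily or almost daily")), 8)
)

#' Select simultaneous alcohol-and-cannabis users
#'
#' Respondents answering the screening item ("how often did you take
#' alcohol along with cannabis?") with "hardly ever" or any more frequent
#' category are retained; "never" and missing answers are excluded.
#'
#' @param answers Character vector of screening answers; `NA` allowed.
#' @return Logical mask, `TRUE` for retained respondents.
#' @export
select_simultaneous_users <- function(answers) {
  ans <- as.character(answers)
  bad <- !is.na(ans) & !(ans %in% simultaneous_use_levels)
  if (any(bad)) {
    stop("unknown screening category: ",
         paste(sQuote(unique(ans[bad])), collapse = ", "))
  }
  !is.na(ans) & ans != "never"
}

#' Dichotomize an ordinal CUDIT answer to symptom presence/absence
#'
#' Items 3-10: "never" codes absence (0), anything more frequent presence
#' (1). Items 1 and 2 have no "never" option (respondents are cannabis
#' users), so only the single lowest category of each ("less than a
#' month", "one or two h") codes absence.
#'
#' @param item_id Integer in 1..10.
#' @param answers Character vector of answers on the item's scale.
#' @return Integer vector of 0/1; `NA` propagates.
#' @export
dichotomize_cudit <- function(item_id, answers) {
  if (length(item_id) != 1L || !item_id %in% 1:10) {
    stop("item_id must be a single integer in 1..10")
  }
  scale <- cudit_scales[[item_id]]
  ans <- as.character(answers)
  bad <- !is.na(ans) & !(ans %in% scale)
  if (any(bad)) {
    stop("answer not on the scale of CUDIT item ", item_id, ": ",
         paste(sQuote(unique(ans[bad])), collapse = ", "))
  }
  out <- ifelse(is.na(ans), NA_integer_, as.integer(ans != scale[1L]))
  out
}

#' Binary symptom data container
#'
#' @param x Numeric or integer matrix of 0/1 values, respondents in rows.
#' @param labels Character vector of unique symptom labels (one per
#'   column); defaults to the column names.
#' @param disorder Optional disorder membership per symptom (e.g.
#'   `"alcohol"` / `"cannabis"`); inferred from a leading `A`/`C` in the
#'   label when `NULL` and the labels allow it.
#' @return An object of class `symptom_data`: list with elements `x`
#'   (integer matrix), `labels`, `disorder`, `n`, `p`.
#' @export
symptom_data <- function(x, labels = colnames(x), disorder = NULL) {
  x <- as.matrix(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(labels)) stop("symptom labels must be unique")
  if (length(labels) != ncol(x)) stop("one label per column required")
  if (anyNA(x)) stop("symptom_data does not allow missing entries; use prepare_symptoms()")
  if (!all(x %in% c(0L, 1L))) stop("entries must be 0/1")
  storage.mode(x) <- "integer"
  colnames(x) <- labels
  if (is.null(disorder)) {
    pre <- substr(labels, 1L, 1L)
    if (all(pre %in% c("A", "C"))) {
      disorder <- ifelse(pre == "A", "alcohol", "cannabis")
    }
  }
  if (!is.null(disorder) && length(disorder) != ncol(x)) {
    stop("one disorder label per symptom required")
  }
  structure(
    list(x = x, labels = labels, disorder = disorder,
         n = nrow(x), p = ncol(x)),
    class = "symptom_data"
  )
}

#' @export
print.symptom_data <- function(x, ...) {
  cat("symptom_data:", x$n, "respondents x", x$p, "symptoms\n")
  rate <- colMeans(x$x)
  cat("endorsement:", paste0(x$labels, "=",
      sprintf("%.1f%%", 100 * rate), collapse = " "), "\n")
  invisible(x)
}

#' Prepare a raw binary matrix for network estimation
#'
#' Applies listwise deletion (any respondent with a missing value is
#' dropped) and removes zero-variance columns (symptoms endorsed by all or
#' by none), which carry no information for conditional-association
#' estimation. Both steps are reported in a preparation log.
#'
#' @param x Matrix or data frame with entries in `{0, 1, NA}`.
#' @param labels,disorder Passed to [symptom_data()].
#' @param min_rows Minimum retained sample size (default 50).
#' @return List with `data` (a [symptom_data()] object) and `log`, a list
#'   holding `n_dropped_rows`, `dropped_columns` (data frame of label and
#'   reason), and `endorsement` (named rates of retained columns).
#' @export
prepare_symptoms <- function(x, labels = colnames(x), disorder = NULL,
                             min_rows = 50) {
  x <- as.matrix(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
  ok_vals <- x %in% c(0, 1) | is.na(x)
  if (!all(ok_vals)) stop("entries must be 0, 1 or missing")
  keep_row <- !apply(x, 1L, anyNA)
  n_dropped <- sum(!keep_row)
  x <- x[keep_row, , drop = FALSE]
  rate <- colMeans(x)
  zero_var <- rate == 0 | rate == 1
  dropped_cols <- data.frame(
    label = labels[zero_var],
    reason = ifelse(rate[zero_var] == 1,
                    "no variance (endorsed by all)",
                    "no variance (endorsed by none)"),
    stringsAsFactors = FALSE
  )
  x <- x[, !zero_var, drop = FALSE]
  keep_lab <- labels[!zero_var]
  keep_dis <- if (!is.null(disorder)) disorder[!zero_var] else NULL
  if (ncol(x) < 2L) stop("fewer than 2 symptoms retain variance after preparation")
  if (nrow(x) < min_rows) {
    stop("only ", nrow(x), " complete respondents retained (minimum ", min_rows, ")")
  }
  dat <- symptom_data(x, labels = keep_lab, disorder = keep_dis)
  list(
    data = dat,
    log = list(
      n_dropped_rows = n_dropped,
      dropped_columns = dropped_cols,
      endorsement = setNames(colMeans(x), keep_lab)
    )
  )
}

#' Scale reliability: KR-20 and Spearman-Brown split-half
#'
#' Kuder-Richardson formula 20,
#' `K/(K-1) * (1 - sum(p_i q_i) / sigma^2)`, with `sigma^2` the
#' population (divide-by-n) variance of the total score, and the
#' Spearman-Brown-corrected correlation `2r/(1+r)` between total scores
#' on two random halves of the item set (sizes `ceiling(K/2)` and
#' `floor(K/2)`, drawn under `split_seed`).
#'
#' @param data A [symptom_data()] object or 0/1 matrix (at least 2 items
#'   and 2 respondents).
#' @param split_seed Integer seed for the random item split.
#' @return List of class `reliability_report`: `kr20`, `split_half`,
#'   `item_props`, `total_score_variance`, `split` (the two item index
#'   sets), `half_correlation`.
#' @export
reliability <- function(data, split_seed = 1L) {
  x <- if (inherits(data, "symptom_data")) data$x else as.matrix(data)
  n <- nrow(x); K <- ncol(x)
  if (K < 2L || n < 2L) stop("need at least 2 items and 2 respondents")
  p <- colMeans(x)
  total <- rowSums(x)
  s2 <- mean((total - mean(total))^2)
  if (s2 <= 0) stop("total-score variance is zero; reliability undefined")
  kr20 <- K / (K - 1) * (1 - sum(p * (1 - p)) / s2)
  set.seed(split_seed)
  first <- sort(sample.int(K, ceiling(K / 2)))
  second <- setdiff(seq_len(K), first)
  r <- cor(rowSums(x[, first, drop = FALSE]),
           rowSums(x[, second, drop = FALSE]))
  structure(
    list(kr20 = kr20, split_half = spearman_brown(r),
         item_props = p, total_score_variance = s2,
         split = list(first = first, second = second),
         half_correlation = r),
    class = "reliability_report"
  )
}

#' Spearman-Brown correction of a half-test correlation
#'
#' @param r Correlation between two half-test scores.
#' @return `2 r / (1 + r)`.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("KR-20 = %.3f, Spearman-Brown split-half = %.3f\n",
              x$kr20, x$split_half))
  invisible(x)
}

#' Read a respondent-by-symptom CSV
#'
#' Header row of symptom labels, one respondent per row; empty cells and
#' the string "NA" are treated as missing.
#'
#' @param path CSV file path.
#' @param ... Passed to [prepare_symptoms()].
#' @return As [prepare_symptoms()].
#' @export
read_symptom_csv <- function(path, ...) {
  x <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  prepare_symptoms(as.matrix(x), labels = colnames(x), ...)
}

#' Write symptom data as CSV
#' @param data A [symptom_data()] object.
#' @param path Output path.
#' @export
write_symptom_csv <- function(data, path) {
  write.csv(as.data.frame(data$x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
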