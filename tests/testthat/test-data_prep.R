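test_that("simultaneous-use screening follows the 'hardly ever or more' rule", {
  ans <- c("never", "hardly ever", "seldom", "more or less half of the time",
           "often", "almost always", NA)
  expect_identical(select_simultaneous_users(ans),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(select_simultaneous_users(c("never", "sometimes")),
               "sometimes")
})

test_that("CUDIT dichotomization: lowest category is absence, items 1-2 special", {
  expect_identical(dichotomize_cudit(3, c("never", "less than a month",
                                          "daily or almost daily")),
                   c(0L, 1L, 1L))
  expect_identical(dichotomize_cudit(1, c("less than a month", "monthly",
                                          "weekly")),
                   c(0L, 1L, 1L))
  expect_identical(dichotomize_cudit(2, c("one or two h", "three or four h",
                                          "seven h or more")),
                   c(0L, 1L, 1L))
  expect_identical(dichotomize_cudit(5, NA_character_), NA_integer_)
  expect_error(dichotomize_cudit(3, "one or two h"), "item 3")
  expect_error(dichotomize_cudit(0, "never"), "item_id")
})

test_that("prepare_symptoms drops incomplete rows and zero-variance columns", {
  set.seed(42)
  x <- matrix(rbinom(300, 1, 0.4), 100, 3,
              dimnames = list(NULL, c("A1", "A2", "C1")))
  x_aug <- cbind(x, C2 = 1L, C3 = 0L)
  x_aug[3, 1] <- NA
  res <- prepare_symptoms(x_aug, min_rows = 10)
  expect_equal(res$data$n, 99)
  expect_equal(res$data$labels, c("A1", "A2", "C1"))
  expect_equal(res$log$n_dropped_rows, 1)
  expect_setequal(res$log$dropped_columns$label, c("C2", "C3"))
  expect_match(res$log$dropped_columns$reason[
    res$log$dropped_columns$label == "C2"], "endorsed by all")
  # complete mixed matrix passes through unchanged
  res2 <- prepare_symptoms(x, min_rows = 10)
  expect_equal(unname(res2$data$x), unname(x), ignore_attr = TRUE)
  expect_equal(res2$log$n_dropped_rows, 0)
})

test_that("prepare_symptoms is idempotent and dropping columns preserves rates", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rbinom(400, 1, runif(4, 0.1, 0.9)), 100, 4,
                dimnames = list(NULL, paste0("A", 1:4)))
    x <- cbind(x, A5 = 0L)
    r1 <- prepare_symptoms(x, min_rows = 10)
    r2 <- prepare_symptoms(r1$data$x, min_rows = 10)
    expect_identical(r1$data$x, r2$data$x)
    expect_equal(r1$log$endorsement, colMeans(x[, colnames(r1$data$x)]))
  }
})

test_that("prepare_symptoms errors on degenerate input", {
  x <- matrix(c(0, 1, 0, 1), 4, 1, dimnames = list(NULL, "A1"))
  expect_error(prepare_symptoms(cbind(x, A2 = 1L), min_rows = 2),
               "fewer than 2")
  x2 <- matrix(rbinom(20, 1, 0.5), 10, 2, dimnames = list(NULL, c("A1", "A2")))
  expect_error(prepare_symptoms(x2, min_rows = 50), "minimum 50")
  expect_error(prepare_symptoms(matrix(c(0, 2), 2, 1)), "0, 1 or missing")
})

test_that("KR-20 matches its defining formula and edge cases", {
  # K identical items with p = 0.5 -> perfectly parallel -> 1
  col <- rep(c(0L, 1L), 10)
  expect_equal(reliability(cbind(col, col, col, col))$kr20, 1)
  # orthogonal balanced items: total variance equals sum of item variances
  x <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(reliability(x)$kr20, 0)
  # direct-formula oracle on arbitrary data
  set.seed(9)
  y <- matrix(rbinom(60, 1, 0.4), 12, 5)
  y[1, ] <- 1  # guarantee variance
  rep_ <- reliability(y, split_seed = 4)
  K <- ncol(y)
  pq <- colMeans(y) * (1 - colMeans(y))
  tot <- rowSums(y)
  s2 <- sum((tot - mean(tot))^2) / length(tot)
  expect_equal(rep_$kr20, K / (K - 1) * (1 - sum(pq) / s2), tolerance = 1e-12)
})

test_that("split-half reliability is seeded and Spearman-Brown corrected", {
  expect_equal(spearman_brown(0.6), 0.75)
  set.seed(11)
  y <- matrix(rbinom(500, 1, 0.5), 100, 5)
  a <- reliability(y, split_seed = 2)
  b <- reliability(y, split_seed = 2)
  expect_identical(a$split, b$split)
  expect_equal(lengths(a$split), c(first = 3L, second = 2L))
  expect_equal(a$split_half, spearman_brown(a$half_correlation))
  expect_error(reliability(matrix(0L, 10, 2)), "variance")
})

test_that("symptom CSV round-trips through the preparation dialect", {
  set.seed(3)
  x <- matrix(rbinom(200, 1, 0.3), 50, 4,
              dimnames = list(NULL, c("A1", "A2", "C1", "C2")))
  f <- tempfile(fileext = ".csv")
  write_symptom_csv(symptom_data(x), f)
  back <- read_symptom_csv(f, min_rows = 10)
  expect_equal(unname(back$data$x), unname(x))
  expect_equal(back$data$disorder, c("alcohol", "alcohol", "cannabis",
                                     "cannabis"))
})
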