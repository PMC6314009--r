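test_that("enumeration reproduces closed-form probabilities", {
  # two independent symmetric nodes: uniform over the 4 states
  p2 <- ising_params(c(0, 0), matrix(0, 2, 2))
  expect_equal(ising_pmf(p2), rep(0.25, 4))
  # coupling ln 3: unnormalized weights (1, 1, 1, 3)
  p2c <- ising_params(c(0, 0), matrix(c(0, log(3), log(3), 0), 2))
  expect_equal(ising_pmf(p2c), c(1, 1, 1, 3) / 6)
  # single node, tau = ln 9 -> P(1) = 0.9
  p1 <- ising_params(log(9), matrix(0, 1, 1))
  expect_equal(ising_pmf(p1), c(0.1, 0.9))
})

test_that("pmf sums to one and marginals are label-equivariant", {
  for (s in 1:5) {
    set.seed(s)
    p <- sample(3:12, 1)
    om <- random_weights(p, seed = s + 100, density = 0.5)
    pars <- ising_params(rnorm(p), om)
    pmf <- ising_pmf(pars)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    m <- ising_marginals(pars)
    perm <- sample(p)
    pars_p <- ising_params(pars$tau[perm], om[perm, perm])
    expect_equal(unname(ising_marginals(pars_p)), unname(m[perm]),
                 tolerance = 1e-12)
    # marginals agree with the pmf-derived ones
    sm <- state_matrix(seq_along(pmf) - 1L, p)
    expect_equal(unname(m), colSums(sm * pmf), tolerance = 1e-12)
  }
})

test_that("conditional logit is the Bayes-rule conditional of the joint", {
  pars <- ising_params(c(0.3, -0.2), matrix(c(0, 0.8, 0.8, 0), 2))
  cond <- ising_conditional(pars, 1)
  expect_equal(cond$intercept, 0.3)
  expect_equal(unname(cond$coefficients), 0.8)
  # zero couplings: conditional reduces to the marginal logit
  ind <- ising_params(c(1, -1, 0.5), matrix(0, 3, 3))
  expect_equal(unname(ising_conditional(ind, 2)$coefficients), c(0, 0))
  # enumeration route for one random model
  set.seed(77)
  p <- 5
  pars <- ising_params(rnorm(p), random_weights(p, 7, density = 0.7))
  pmf <- ising_pmf(pars)
  sm <- state_matrix(seq_along(pmf) - 1L, p)
  for (i in seq_len(p)) {
    others <- sm[sm[, i] == 0, -i, drop = FALSE]
    idx1 <- which(sm[, i] == 1)
    idx0 <- which(sm[, i] == 0)
    cond_enum <- pmf[idx1] / (pmf[idx1] + pmf[idx0])
    cl <- ising_conditional(pars, i)
    eta <- cl$intercept + as.vector(others %*% cl$coefficients)
    expect_equal(cond_enum, 1 / (1 + exp(-eta)), tolerance = 1e-12)
  }
})

test_that("exact sampling is seeded and matches the model's marginals", {
  lg <- function(q) log(q / (1 - q))
  pars <- ising_params(lg(c(0.2, 0.5, 0.7)), matrix(0, 3, 3))
  n <- 20000
  s1 <- ising_sample(pars, n, seed = 5)
  s2 <- ising_sample(pars, n, seed = 5)
  expect_identical(s1$x, s2$x)
  se <- sqrt(c(0.2, 0.5, 0.7) * c(0.8, 0.5, 0.3) / n)
  expect_true(all(abs(colMeans(s1$x) - c(0.2, 0.5, 0.7)) < 3 * se))
})

test_that("positive coupling raises the empirical odds ratio above its null", {
  om <- matrix(c(0, 1.5, 1.5, 0), 2)
  pars <- ising_params(c(-0.5, -0.5), om)
  s <- ising_sample(pars, 5000, seed = 3)
  tab <- table(factor(s$x[, 1], 0:1), factor(s$x[, 2], 0:1))
  emp_or <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  # population odds ratio from enumeration is exp(omega12)
  expect_gt(emp_or, 1)
  expect_equal(log(emp_or), 1.5, tolerance = 0.25)
})

test_that("gibbs sampling agrees with enumeration and validates inputs", {
  set.seed(1)
  pars <- ising_params(rnorm(5, -0.5), random_weights(5, 21, density = 0.5,
                                                      signed = FALSE))
  m <- unname(ising_marginals(pars))
  n_keep <- 50000
  g <- ising_sample(pars, n_keep, seed = 8, method = "gibbs", thin = 1,
                    burnin = 500)
  se <- sqrt(m * (1 - m) / n_keep)
  # thinning 1 autocorrelates draws; allow inflated Monte-Carlo error
  expect_true(all(abs(colMeans(g$x) - m) < 6 * se))
  expect_error(ising_sample(pars, 10, method = "gibbs", thin = 0), "thin")
  big <- ising_params(rep(0, 21), matrix(0, 21, 21))
  expect_error(ising_sample(big, 5, method = "exact"), "p <= 20")
})

test_that("threshold calibration reaches the targets", {
  # no couplings, targets 0.5 -> tau 0
  pars <- ising_params(rep(1, 4), matrix(0, 4, 4))
  cal <- calibrate_thresholds(pars, rep(0.5, 4))
  expect_true(all(abs(cal$tau) < 0.05))
  # coupled model: marginals land within tolerance
  om <- random_weights(6, 31, density = 0.6, signed = FALSE)
  targ <- c(0.15, 0.3, 0.45, 0.2, 0.35, 0.5)
  cal2 <- calibrate_thresholds(ising_params(rep(0, 6), om), targ)
  expect_true(all(abs(ising_marginals(cal2) - targ) <= 0.005))
  expect_error(calibrate_thresholds(ising_params(rep(0, 6), 3 * om), targ,
                                    max_rounds = 1),
               "did not converge")
})

test_that("the study-like generator emulates the two-disorder structure", {
  cfg <- cohort_config(seed = 4)
  tr <- study_parameters(cfg)
  expect_equal(tr$params$labels, c(paste0("A", 1:11), paste0("C", 1:10)))
  expect_equal(table(tr$disorder), table(rep(c("alcohol", "cannabis"),
                                             c(11, 10))))
  expect_equal(sum(tr$edges$type == "bridge"), 3)
  # bridge weights descend so a unique strongest bridge exists
  bw <- tr$edges$weight[tr$edges$type == "bridge"]
  expect_equal(bw, 1.5 * c(1, 0.7, 0.4))
  # no-bridge config zeroes the whole between block
  tr0 <- study_parameters(cohort_config(seed = 4, n_bridge_edges = 0))
  between <- tr0$params$omega[1:11, 12:21]
  expect_true(all(between == 0))
  # calibration hit the published-style endorsement profile
  expect_true(all(abs(ising_marginals(tr$params) -
                        cfg$target_endorsement_rates) <= 0.005))
})

test_that("the zero-variance flag injects an all-ones column", {
  sim <- simulate_cohort(small_config(seed = 2,
                                      include_zero_variance_column = TRUE))
  expect_true(all(sim$data$x[, sim$data$p] == 1))
  prep <- prepare_symptoms(sim$data$x, labels = sim$data$labels,
                           min_rows = 10)
  expect_equal(prep$log$dropped_columns$label, sim$data$labels[sim$data$p])
})
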