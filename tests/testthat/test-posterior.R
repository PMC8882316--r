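test_that("conjugate Beta update follows the closed form and validates input", {
  expect_equal(update_beta(beta_params(1, 1), 12, 40),
               beta_params(13, 29))
  # no data leaves the prior unchanged
  expect_equal(update_beta(beta_params(1, 1), 0, 0), beta_params(1, 1))
  expect_equal(update_beta(beta_params(2, 3), 5, 12), beta_params(7, 10))
  expect_error(update_beta(beta_params(1, 1), 5, 3), "exceed")
  expect_error(update_beta(beta_params(1, 1), -1, 3), "nonnegative")
  expect_error(beta_params(0, 1), "positive")
})

test_that("posterior draws match closed-form moments and are matched/reproducible", {
  cts <- subset_arm_counts(
    events = matrix(c(40, 20, 30, 25), 2,
                    dimnames = list(NULL, c("A", "B"))),
    totals = matrix(100, 2, 2))
  d <- sample_posterior(cts, n_draws = 20000, seed = 42)
  # empirical means of p_jk vs (alpha + y) / (alpha + beta + n)
  for (k in c("A", "B")) {
    for (arm in c("control", "experimental")) {
      post <- update_beta(beta_params(1, 1), cts$events[arm, k],
                          cts$totals[arm, k])
      m <- post$alpha / (post$alpha + post$beta)
      sd_mc <- sqrt(m * (1 - m) / 20000) * 1.2  # conservative MC band
      emp <- mean(if (arm == "control") d$p_control[, k]
                  else d$p_experimental[, k])
      expect_lt(abs(emp - m), 4 * sd_mc)
    }
  }
  # matched sampling: theta draws re-derivable from the stored p draws
  expect_identical(d$theta, d$p_experimental / d$p_control)
  expect_identical(d$log_theta, log(d$theta))
  # bitwise reproducibility
  d2 <- sample_posterior(cts, n_draws = 20000, seed = 42)
  expect_identical(d$theta, d2$theta)
  expect_identical(d$theta_global, d2$theta_global)
})

test_that("posterior mean of theta matches an independent quadrature oracle", {
  # y1 = 20/100 vs y0 = 40/100 with Beta(1,1) priors:
  # E[theta] = E[p1] * E[1/p0], each factor by numerical integration of the
  # corresponding Beta density
  cts <- subset_arm_counts(events = matrix(c(40, 20), 2),
                           totals = matrix(c(100, 100), 2))
  e_p1 <- stats::integrate(function(x) x * stats::dbeta(x, 21, 81), 0, 1)$value
  e_inv_p0 <- stats::integrate(function(x) stats::dbeta(x, 41, 61) / x,
                               0, 1)$value
  d <- sample_posterior(cts, n_draws = 40000, seed = 9)
  mc_se <- stats::sd(d$theta[, 1]) / sqrt(40000)
  expect_lt(abs(mean(d$theta[, 1]) - e_p1 * e_inv_p0), 4 * mc_se)
})

test_that("exchangeable arms put half the posterior mass below theta = 1", {
  cts <- subset_arm_counts(events = matrix(c(30, 30, 12, 12), 2,
                                           dimnames = list(NULL, c("A", "B"))),
                           totals = matrix(c(80, 80, 40, 40), 2))
  d <- sample_posterior(cts, n_draws = 20000, seed = 5)
  expect_lt(abs(influence_probability(d, "A", lam = 1) - 0.5),
            4 * sqrt(0.25 / 20000))
})

test_that("zero events in the control arm still give finite positive ratios", {
  cts <- subset_arm_counts(events = matrix(c(0, 5, 3, 3), 2,
                                           dimnames = list(NULL, c("A", "B"))),
                           totals = matrix(c(20, 20, 10, 10), 2))
  d <- sample_posterior(cts, n_draws = 5000, seed = 3)
  expect_true(all(is.finite(d$theta)))
  expect_true(all(d$theta > 0))
})

test_that("influence probability behaves as a CDF of the theta draws", {
  d <- sample_posterior(counts_strong_A(), n_draws = 5000, seed = 7)
  expect_identical(influence_probability(d, "A", max(d$theta[, "A"]) * 1.01), 1)
  expect_identical(influence_probability(d, "A", min(d$theta[, "A"]) * 0.99), 0)
  # monotone nondecreasing in lambda
  lams <- c(0.25, 0.5, 0.75, 1, 1.5)
  p <- vapply(lams, function(l) influence_probability(d, "A", l), numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_error(influence_probability(d, "Z", 0.9), "unknown subset")
})

test_that("large balanced counts make log theta approximately normal", {
  # delta-method normal oracle: mu = log RR, sigma^2 = 1/y1 - 1/n1 + 1/y0 - 1/n0
  cts <- subset_arm_counts(events = matrix(c(400, 300, 100, 100), 2,
                                           dimnames = list(NULL, c("A", "B"))),
                           totals = matrix(c(1000, 1000, 300, 300), 2))
  d <- sample_posterior(cts, n_draws = 30000, seed = 12)
  mu <- log((300 / 1000) / (400 / 1000))
  sigma <- sqrt(1 / 300 - 1 / 1000 + 1 / 400 - 1 / 1000)
  for (lam in c(0.8, 0.9, 1.0)) {
    expect_lt(abs(influence_probability(d, "A", lam) -
                    stats::pnorm((log(lam) - mu) / sigma)), 0.02)
  }
})

test_that("posterior estimates report means with equal-tailed 95% intervals", {
  d <- sample_posterior(counts_strong_A(), n_draws = 8000, seed = 2)
  est <- posterior_estimates(d)
  expect_equal(est$subset, c("A", "B", "global"))
  a <- est[est$subset == "A", ]
  expect_equal(a$theta_hat, mean(d$theta[, "A"]))
  expect_equal(a$lower, unname(quantile(d$theta[, "A"], 0.025)))
  expect_true(all(est$lower < est$theta_hat & est$theta_hat < est$upper))
})
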