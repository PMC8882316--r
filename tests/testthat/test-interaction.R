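# Brute-force loop oracles for every interaction probability: the vectorized
# implementations must agree with a direct loop over draws to machine
# precision.

brute_millen <- function(theta_k, theta_t, eta) {
  num <- den <- 0
  for (i in seq_along(theta_k)) {
    if (theta_t[i] >= theta_k[i]) {
      den <- den + 1
      if (theta_t[i] / theta_k[i] > eta) num <- num + 1
    }
  }
  if (den == 0) 0 else num / den
}

brute_quali <- function(beta, sigma, c1) {
  hits <- 0
  for (i in seq_len(nrow(beta))) {
    qm <- qp <- 0
    for (k in seq_len(ncol(beta))) {
      z2 <- (beta[i, k] / sigma[k])^2
      if (beta[i, k] < 0) qm <- qm + z2
      if (beta[i, k] > 0) qp <- qp + z2
    }
    if (min(qm, qp) > c1) hits <- hits + 1
  }
  hits / nrow(beta)
}

brute_quanti <- function(theta, theta_global, c2) {
  hits <- 0
  for (i in seq_len(nrow(theta))) {
    if (sum(theta[i, ] - theta_global[i]) > c2) hits <- hits + 1
  }
  hits / nrow(theta)
}

test_that("Millen probability handles the degenerate and constructed cases", {
  v <- c(0.5, 0.8, 1.2, 0.9, 1.1)
  # identical draw vectors: ratio is exactly 1, never > eta = 1
  d <- make_draws(cbind(A = v, B = v))
  m <- millen_probability(d, "A", "B", eta = 1)
  expect_identical(m$probability, 0)
  expect_identical(m$conditioning_fraction, 1)
  # theta_t = 2 * theta_k elementwise: ratio exactly 2 everywhere
  d2 <- make_draws(cbind(A = v, B = 2 * v))
  expect_identical(millen_probability(d2, "A", "B", eta = 1.5)$probability, 1)
  # empty conditioning event warns and returns 0/0
  d3 <- make_draws(cbind(A = v + 1, B = v))
  expect_warning(m3 <- millen_probability(d3, "A", "B", eta = 1.1),
                 "conditioning event")
  expect_identical(m3$probability, 0)
  expect_identical(m3$conditioning_fraction, 0)
})

test_that("Millen probability equals the double-filter loop oracle exactly", {
  set.seed(81)
  for (rep in 1:5) {
    th <- cbind(A = exp(rnorm(400, -0.2, 0.4)), B = exp(rnorm(400, 0.1, 0.4)))
    d <- make_draws(th)
    for (eta in c(1, 1.1, 1.3, 2)) {
      expect_identical(millen_probability(d, "A", "B", eta)$probability,
                       brute_millen(th[, "A"], th[, "B"], eta))
    }
    # monotone nonincreasing in eta
    p <- vapply(c(1, 1.1, 1.3, 2), function(e)
      millen_probability(d, "A", "B", e)$probability, numeric(1))
    expect_true(all(diff(p) <= 0))
    # the two mirrored conditioning fractions sum to >= 1 (ties in both)
    f <- millen_probability(d, "A", "B", 1.1)$conditioning_fraction +
      millen_probability(d, "B", "A", 1.1)$conditioning_fraction
    expect_gte(f, 1)
  }
})

test_that("Gail-Simon per-draw statistics split the standardized terms by sign", {
  set.seed(5)
  th <- cbind(A = exp(rnorm(300, -0.3, 0.3)), B = exp(rnorm(300, 0.2, 0.3)),
              C = exp(rnorm(300, 0, 0.3)))
  d <- make_draws(th)
  gs <- gail_simon_draws(d)
  expect_equal(gs$sigma_k, apply(log(th), 2, sd))
  expect_true(all(gs$q_minus >= 0 & gs$q_plus >= 0))
  # algebraic identity: Q- + Q+ = sum_k (beta_k / sigma_k)^2 (no beta is 0)
  z2 <- sweep(log(th), 2, gs$sigma_k, "/")^2
  expect_equal(gs$q_minus + gs$q_plus, rowSums(z2))
  # manual per-draw check on one draw
  i <- 17
  b <- log(th)[i, ]
  expect_equal(gs$q_minus[i],
               sum((b[b < 0] / gs$sigma_k[b < 0])^2))
  # all-beneficial draws zero out Q+
  d_neg <- make_draws(cbind(A = exp(-abs(rnorm(100)) - 0.01),
                            B = exp(-abs(rnorm(100)) - 0.01)))
  gs_neg <- gail_simon_draws(d_neg)
  expect_true(all(gs_neg$q_plus == 0))
  expect_identical(quali_probability(gs_neg, 0.5), 0)
  # degenerate zero-variance draws are rejected
  expect_error(gail_simon_draws(make_draws(cbind(A = rep(1, 10),
                                                 B = rep(2, 10)))),
               "degenerate")
})

test_that("qualitative probability matches the loop oracle and its trivial cases", {
  set.seed(23)
  th <- cbind(A = exp(rnorm(500, -0.4, 0.5)), B = exp(rnorm(500, 0.4, 0.5)))
  d <- make_draws(th)
  gs <- gail_simon_draws(d)
  for (c1 in c(0, 0.5, 1, 3)) {
    expect_identical(quali_probability(gs, c1),
                     brute_quali(gs$beta_k, gs$sigma_k, c1))
  }
  # c1 = 0 with opposite-sign betas in every draw
  d_opp <- make_draws(cbind(A = exp(-abs(rnorm(100)) - 0.01),
                            B = exp(abs(rnorm(100)) + 0.01)))
  expect_identical(quali_probability(gail_simon_draws(d_opp), 0), 1)
  # monotone nonincreasing in c1
  p <- vapply(c(0, 0.5, 1, 2, 4), function(c1) quali_probability(gs, c1),
              numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("quantitative probability matches the loop oracle and is symmetric under balance", {
  set.seed(31)
  th <- cbind(A = exp(rnorm(500, -0.2, 0.4)), B = exp(rnorm(500, 0.1, 0.4)))
  g <- exp(rnorm(500, 0, 0.2))
  d <- make_draws(th, theta_global = g)
  for (c2 in c(-1, 0, 0.2, 1)) {
    expect_identical(quanti_probability(d, c2), brute_quanti(th, g, c2))
  }
  # any cutoff below the minimum observed sum gives 1
  expect_identical(quanti_probability(d, min(rowSums(th) - 2 * g) - 1), 1)
  # monotone nonincreasing in c2
  p <- vapply(c(-1, 0, 0.5, 2), function(c2) quanti_probability(d, c2),
              numeric(1))
  expect_true(all(diff(p) <= 0))
  # balanced configuration: identical counts in all subsets, pooled global
  # -> per-draw sum is symmetric about ~0
  cts <- subset_arm_counts(events = matrix(30, 2, 2,
                                           dimnames = list(NULL, c("A", "B"))),
                           totals = matrix(100, 2, 2))
  ds <- sample_posterior(cts, n_draws = 20000, seed = 11)
  expect_lt(abs(quanti_probability(ds, 0) - 0.5), 0.05)
})
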