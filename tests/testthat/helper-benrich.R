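# Shared fixtures, all built in code.

# Hand-built posterior_draws object for interaction-criterion oracles: the
# theta draws are specified directly, with p draws kept consistent so the
# matched-sampling invariant holds.
make_draws <- function(theta, theta_global = NULL, seed = 0L) {
  theta <- as.matrix(theta)
  if (is.null(colnames(theta))) colnames(theta) <- LETTERS[seq_len(ncol(theta))]
  p0 <- matrix(0.4, nrow(theta), ncol(theta), dimnames = dimnames(theta))
  if (is.null(theta_global)) theta_global <- rowMeans(theta)
  structure(list(p_control = p0, p_experimental = p0 * theta, theta = theta,
                 log_theta = log(theta), theta_global = theta_global,
                 n_draws = nrow(theta), seed = seed,
                 subsets = colnames(theta)),
            class = "posterior_draws")
}

# Counts with a strong planted benefit in A (K = 2).
counts_strong_A <- function() {
  subset_arm_counts(
    events = matrix(c(50, 10, 40, 40), 2,
                    dimnames = list(c("control", "experimental"),
                                    c("A", "B"))),
    totals = matrix(100, 2, 2,
                    dimnames = list(c("control", "experimental"),
                                    c("A", "B"))))
}

# Unreachable thresholds: probabilities can never strictly exceed 1.
thr_unreachable <- function(rule = "millen") {
  if (rule == "millen") {
    enrich_thresholds(gamma = 1, eta = 1, tau = 1, rule = "millen")
  } else {
    enrich_thresholds(gamma = 1, epsilon = 1, c1 = 1, c2 = 0.1,
                      rule = "gail_simon")
  }
}

# Permissive Millen thresholds that fire on any clear effect.
thr_easy <- function() {
  enrich_thresholds(gamma = 0.5, eta = 1.1, tau = 0.5, rule = "millen")
}

scen2 <- function() k2_scenarios()$scenario2
scen4 <- function() k2_scenarios()$scenario4
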