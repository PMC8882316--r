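# Conjugate Beta-binomial posterior machinery.
#
# Within each biomarker subset k the probability of an unfavorable outcome
# (e.g. death) in arm j is p_jk with a Beta prior; the subset-level treatment
# effect is the relative risk theta_k = p_1k / p_0k (experimental over
# control), theta_k < 1 favoring the experimental arm.  Because the model is
# fully conjugate, the posterior of every p_jk is Beta and exact independent
# Monte Carlo draws replace MCMC.

#' Beta distribution parameters
#'
#' Container for the shape parameters of a Beta prior or posterior on an
#' arm-by-subset response probability.
#'
#' @param alpha,beta positive shape parameters.  The non-informative
#'   `beta_params(1, 1)` is the default prior throughout the package.
#' @return An object of class `beta_params`.
#' @examples
#' beta_params(1, 1)
#' @export
beta_params <- function(alpha = 1, beta = 1) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1L ||
      length(beta) != 1L || !is.finite(alpha) || !is.finite(beta) ||
      alpha <= 0 || beta <= 0) {
    stop("Beta shape parameters must be single positive finite numbers",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)\n", x$alpha, x$beta))
  invisible(x)
}

#' Conjugate Beta-binomial update
#'
#' Updates a Beta prior with binomial data: `events` responses out of
#' `totals` patients yield a `Beta(alpha + events, beta + totals - events)`
#' posterior.
#'
#' @param prior a [beta_params()] object.
#' @param events nonnegative integer number of responses.
#' @param totals nonnegative integer number of patients, `>= events`.
#' @return The posterior as a [beta_params()] object.
#' @examples
#' update_beta(beta_params(1, 1), events = 12, totals = 40)  # Beta(13, 29)
#' @export
update_beta <- function(prior, events, totals) {
  if (!inherits(prior, "beta_params")) prior <- do.call(beta_params, as.list(prior))
  .assert_count(events, "events")
  .assert_count(totals, "totals")
  if (length(events) != 1L || length(totals) != 1L) {
    stop("'events' and 'totals' must be scalars", call. = FALSE)
  }
  if (events > totals) stop("'events' cannot exceed 'totals'", call. = FALSE)
  beta_params(prior$alpha + events, prior$beta + totals - events)
}

#' Arm-by-subset sufficient statistics
#'
#' Holds the event counts y_jk and patient totals n_jk per treatment arm and
#' biomarker subset at an analysis — the sufficient statistics of the
#' Beta-binomial model.
#'
#' @param events,totals 2 x K numeric matrices of nonnegative integers with
#'   rows `c("control", "experimental")` (arms 0 and 1) and one column per
#'   subset; column names are the subset labels.
#' @return An object of class `subset_arm_counts`.
#' @export
subset_arm_counts <- function(events, totals) {
  events <- as.matrix(events); totals <- as.matrix(totals)
  .assert_count(events, "events"); .assert_count(totals, "totals")
  if (!all(dim(events) == dim(totals))) {
    stop("'events' and 'totals' must have identical dimensions", call. = FALSE)
  }
  if (nrow(events) != 2L) stop("counts need exactly 2 arm rows", call. = FALSE)
  if (ncol(events) < 1L) stop("counts need at least one subset", call. = FALSE)
  if (any(events > totals)) {
    stop("every cell must satisfy events <= totals", call. = FALSE)
  }
  rownames(events) <- rownames(totals) <- c("control", "experimental")
  if (is.null(colnames(events))) {
    colnames(events) <- colnames(totals) <- LETTERS[seq_len(ncol(events))]
  } else {
    colnames(totals) <- colnames(events)
  }
  structure(list(events = events, totals = totals,
                 subsets = colnames(events)),
            class = "subset_arm_counts")
}

#' @export
print.subset_arm_counts <- function(x, ...) {
  cat("Arm-by-subset counts (events / totals):\n")
  m <- matrix(sprintf("%d/%d", x$events, x$totals), nrow = 2,
              dimnames = dimnames(x$events))
  print(m, quote = FALSE)
  invisible(x)
}

# Restrict counts to a subset of the biomarker subsets.
restrict_counts <- function(counts, subsets) {
  missing <- setdiff(subsets, counts$subsets)
  if (length(missing)) {
    stop("unknown subset label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  subset_arm_counts(counts$events[, subsets, drop = FALSE],
                    counts$totals[, subsets, drop = FALSE])
}

#' Tabulate patient records into arm-by-subset counts
#'
#' @param records a data frame with columns `subset`, `arm` (0 control /
#'   1 experimental) and `outcome` (0/1).
#' @param subsets character vector fixing the subset label set (so subsets
#'   with zero enrolled patients keep a column); defaults to the labels
#'   present in `records`.
#' @return A [subset_arm_counts()] object.
#' @export
count_records <- function(records, subsets = NULL) {
  if (is.null(subsets)) subsets <- sort(unique(as.character(records$subset)))
  K <- length(subsets)
  ev <- tot <- matrix(0L, 2, K, dimnames = list(c("control", "experimental"),
                                                subsets))
  for (j in 0:1) {
    for (k in seq_len(K)) {
      sel <- records$arm == j & records$subset == subsets[k]
      tot[j + 1L, k] <- sum(sel)
      ev[j + 1L, k]  <- sum(records$outcome[sel])
    }
  }
  subset_arm_counts(ev, tot)
}

#' Exact Monte-Carlo sampling of the joint posterior
#'
#' Draws independent samples from the exact Beta posteriors of every p_jk,
#' forms matched draws of the subset-level relative risks
#' `theta_k = p_1k / p_0k`, and draws the global treatment effect `theta`
#' from the posteriors of the arm-level response probabilities pooled across
#' subsets (or, alternatively, from prevalence-weighted mixtures of the
#' subset-level draws).  The model is conjugate, so these are exact posterior
#' samples with zero autocorrelation — no MCMC is involved.
#'
#' @param counts a [subset_arm_counts()] object.
#' @param prior a [beta_params()] prior, shared by all arm-by-subset cells.
#' @param n_draws number of Monte-Carlo draws (default 10000).
#' @param seed integer seed; the same seed reproduces the draws bitwise.
#' @param global_method how to form the global effect draws: `"pooled"`
#'   (default) pools events and totals across subsets within each arm and
#'   applies the same conjugate update; `"weighted"` averages the matched
#'   p_jk draws with weights proportional to per-subset patient totals.
#' @return An object of class `posterior_draws` with components
#'   `p_control`, `p_experimental`, `theta`, `log_theta` (all
#'   `n_draws` x K matrices with subset-labelled columns),
#'   `theta_global` (length `n_draws`), `n_draws`, `seed` and `subsets`.
#' @export
sample_posterior <- function(counts, prior = beta_params(1, 1),
                             n_draws = 10000, seed = 1L,
                             global_method = c("pooled", "weighted")) {
  stopifnot(inherits(counts, "subset_arm_counts"))
  if (!inherits(prior, "beta_params")) prior <- do.call(beta_params, as.list(prior))
  global_method <- match.arg(global_method)
  if (!is.numeric(n_draws) || n_draws < 1) stop("'n_draws' must be >= 1",
                                                call. = FALSE)
  n_draws <- as.integer(n_draws)
  K <- length(counts$subsets)
  set.seed(as.integer(seed))
  p0 <- p1 <- matrix(NA_real_, n_draws, K,
                     dimnames = list(NULL, counts$subsets))
  for (k in seq_len(K)) {
    post0 <- update_beta(prior, counts$events["control", k],
                         counts$totals["control", k])
    post1 <- update_beta(prior, counts$events["experimental", k],
                         counts$totals["experimental", k])
    p0[, k] <- stats::rbeta(n_draws, post0$alpha, post0$beta)
    p1[, k] <- stats::rbeta(n_draws, post1$alpha, post1$beta)
  }
  theta <- p1 / p0
  if (global_method == "pooled") {
    g0 <- update_beta(prior, sum(counts$events["control", ]),
                      sum(counts$totals["control", ]))
    g1 <- update_beta(prior, sum(counts$events["experimental", ]),
                      sum(counts$totals["experimental", ]))
    theta_global <- stats::rbeta(n_draws, g1$alpha, g1$beta) /
      stats::rbeta(n_draws, g0$alpha, g0$beta)
  } else {
    w <- colSums(counts$totals)
    if (sum(w) == 0) w <- rep(1, K)
    w <- w / sum(w)
    theta_global <- as.vector(p1 %*% w) / as.vector(p0 %*% w)
  }
  structure(list(p_control = p0, p_experimental = p1, theta = theta,
                 log_theta = log(theta), theta_global = theta_global,
                 n_draws = n_draws, seed = as.integer(seed),
                 subsets = counts$subsets),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d draws, %d subsets (%s)\n", x$n_draws,
              length(x$subsets), paste(x$subsets, collapse = ", ")))
  cat("Posterior mean theta_k:",
      paste(sprintf("%s=%.3f", x$subsets, colMeans(x$theta)), collapse = "  "),
      "\n")
  invisible(x)
}

.draw_column <- function(draws, subset) {
  if (!subset %in% draws$subsets) {
    stop("unknown subset label: ", subset, call. = FALSE)
  }
  draws$theta[, subset]
}

#' Posterior influence (efficacy) probability
#'
#' The influence condition measures the treatment effect size in subset k as
#' the posterior probability that the subset-level relative risk falls below
#' a clinically meaningful cutoff lambda:
#' `P_1k = P(theta_k < lambda | Data)`.
#'
#' @param draws a [sample_posterior()] result.
#' @param subset subset label.
#' @param lam positive cutoff lambda defining the effect size of interest
#'   (design default 0.9).
#' @return The Monte-Carlo estimate of `P_1k`, in `[0, 1]`.
#' @export
influence_probability <- function(draws, subset, lam = 0.9) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("'lam' must be a single positive number", call. = FALSE)
  }
  mean(.draw_column(draws, subset) < lam)
}

#' Posterior summaries of the subset-level relative risks
#'
#' Posterior means and equal-tailed 95% credibility intervals (2.5 and 97.5
#' percent quantiles) of each theta_k and of the global theta.
#'
#' @param draws a [sample_posterior()] result.
#' @return A data frame with one row per subset plus a `global` row, and
#'   columns `subset`, `theta_hat`, `lower`, `upper`.
#' @export
posterior_estimates <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  qs <- apply(draws$theta, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  gq <- stats::quantile(draws$theta_global, probs = c(0.025, 0.975),
                        names = FALSE)
  data.frame(subset = c(draws$subsets, "global"),
             theta_hat = c(colMeans(draws$theta), mean(draws$theta_global)),
             lower = c(qs[1, ], gq[1]), upper = c(qs[2, ], gq[2]),
             row.names = NULL, stringsAsFactors = FALSE)
}
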