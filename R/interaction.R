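# Bayesian treatment-by-subset interaction criteria.
#
# Two families are offered, mirroring the design's decision rules:
#   * Millen's conditional ratio criterion (K = 2 only): the posterior
#     probability that the relative-risk ratio between the two subsets
#     exceeds a minimal interaction effect eta, conditional on the ratio
#     being oriented against subset k.
#   * Bayesianized Gail-Simon statistics (any K >= 2): per posterior draw,
#     the classical qualitative interaction sums Q- and Q+ are computed from
#     the standardized log relative risks; their posterior exceedance
#     probabilities flag qualitative (opposite-direction) and quantitative
#     (same-direction, different-magnitude) interactions.

#' Millen's conditional interaction probability (K = 2)
#'
#' For two subsets, the interaction measure is the ratio of subset-level
#' relative risks.  Evaluating enrichment of subset `subset_k` against the
#' complementary subset `subset_t`, the criterion is
#' `P_2k = P(theta_t / theta_k > eta | theta_t >= theta_k, Data)`:
#' a large value means the treatment effect in subset k is markedly more
#' favorable (smaller relative risk) than in the other subset, i.e. k is the
#' sensitive subset.
#'
#' @param draws a [sample_posterior()] result with exactly 2 subsets.
#' @param subset_k candidate sensitive subset.
#' @param subset_t the other subset.
#' @param eta minimal interaction effect, `>= 1`.
#' @return A list with `probability` (the Monte-Carlo `P_2k`) and
#'   `conditioning_fraction` (fraction of draws with
#'   `theta_t >= theta_k`).  If no draw satisfies the conditioning event the
#'   probability is 0 with `conditioning_fraction` 0 and a warning — treated
#'   downstream as absence of interaction evidence.
#' @export
millen_probability <- function(draws, subset_k, subset_t, eta = 1) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(draws$subsets) != 2L) {
    stop("Millen's criterion is defined for exactly K = 2 subsets",
         call. = FALSE)
  }
  if (identical(subset_k, subset_t)) {
    stop("'subset_k' and 'subset_t' must differ", call. = FALSE)
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta < 1) {
    stop("'eta' must be a single number >= 1", call. = FALSE)
  }
  tk <- .draw_column(draws, subset_k)
  tt <- .draw_column(draws, subset_t)
  cond <- tt >= tk
  if (!any(cond)) {
    warning("no posterior draw satisfies the conditioning event theta_t >= theta_k",
            call. = FALSE)
    return(list(probability = 0, conditioning_fraction = 0))
  }
  list(probability = mean(tt[cond] / tk[cond] > eta),
       conditioning_fraction = mean(cond))
}

#' Per-draw Gail-Simon interaction statistics
#'
#' For each posterior draw i, the log relative risks `beta_ki = log theta_ki`
#' are standardized by `sigma_k` and split by sign into the qualitative
#' interaction sums
#' `Q-_i = sum_k 1(beta_ki < 0) (beta_ki / sigma_k)^2` and
#' `Q+_i = sum_k 1(beta_ki > 0) (beta_ki / sigma_k)^2`.
#'
#' By default `sigma_k` is the posterior standard deviation of
#' `log theta_k`, estimated once across all draws and held fixed, so the
#' statistic has a genuine posterior distribution induced by the draws of
#' `beta_k` alone.  A frequentist delta-method plug-in standard error
#' computed from the counts is available via `sigma_method = "plugin"`.
#'
#' @param draws a [sample_posterior()] result with K >= 2 subsets and at
#'   least 2 draws.
#' @param sigma_method `"posterior"` (default) or `"plugin"`.
#' @param counts the [subset_arm_counts()] behind `draws`; required for
#'   `sigma_method = "plugin"`.
#' @return An object of class `gail_simon_draws` with components `beta_k`
#'   (draws x K), `sigma_k` (length K), `q_minus`, `q_plus` (length
#'   `n_draws`).
#' @export
gail_simon_draws <- function(draws, sigma_method = c("posterior", "plugin"),
                             counts = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  sigma_method <- match.arg(sigma_method)
  if (length(draws$subsets) < 2L) {
    stop("Gail-Simon statistics need K >= 2 subsets", call. = FALSE)
  }
  if (draws$n_draws < 2L) {
    stop("at least 2 draws are required to estimate sigma_k", call. = FALSE)
  }
  beta <- draws$log_theta
  if (sigma_method == "posterior") {
    sigma <- apply(beta, 2, stats::sd)
  } else {
    if (is.null(counts)) {
      stop("'counts' is required when sigma_method = \"plugin\"", call. = FALSE)
    }
    y1 <- counts$events["experimental", draws$subsets]
    n1 <- counts$totals["experimental", draws$subsets]
    y0 <- counts$events["control", draws$subsets]
    n0 <- counts$totals["control", draws$subsets]
    if (any(y1 == 0 | y0 == 0)) {
      stop("plug-in sigma_k undefined with zero events in an arm", call. = FALSE)
    }
    sigma <- sqrt(1 / y1 - 1 / n1 + 1 / y0 - 1 / n0)
  }
  if (any(!is.finite(sigma) | sigma <= 0)) {
    stop("sigma_k undefined: degenerate (zero-variance) draws in some subset",
         call. = FALSE)
  }
  z2 <- sweep(beta, 2, sigma, "/")^2
  structure(list(beta_k = beta, sigma_k = stats::setNames(sigma, draws$subsets),
                 q_minus = rowSums(z2 * (beta < 0)),
                 q_plus = rowSums(z2 * (beta > 0)),
                 subsets = draws$subsets),
            class = "gail_simon_draws")
}

#' Posterior probability of qualitative interaction
#'
#' `P_quali = P(min(Q-, Q+) > C1 | Data)`: a qualitative interaction
#' (treatment effects in opposite directions across subsets) makes both sums
#' large simultaneously.
#'
#' @param gs a [gail_simon_draws()] result.
#' @param c1 nonnegative cutoff C1 (from calibration).
#' @return Monte-Carlo probability in `[0, 1]`.
#' @export
quali_probability <- function(gs, c1) {
  stopifnot(inherits(gs, "gail_simon_draws"))
  if (!is.numeric(c1) || length(c1) != 1L || c1 < 0) {
    stop("'c1' must be a single nonnegative number", call. = FALSE)
  }
  mean(pmin(gs$q_minus, gs$q_plus) > c1)
}

#' Posterior probability of quantitative interaction
#'
#' `P_quanti = P(sum_k (theta_k - theta) > C2 | Data)`, where theta is the
#' global treatment effect: per posterior draw, the summed deviation of the
#' subset-level relative risks from the global relative risk.
#'
#' @param draws a [sample_posterior()] result (must carry global draws).
#' @param c2 cutoff C2 (from calibration).
#' @return Monte-Carlo probability in `[0, 1]`.
#' @export
quanti_probability <- function(draws, c2) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!is.numeric(c2) || length(c2) != 1L || !is.finite(c2)) {
    stop("'c2' must be a single finite number", call. = FALSE)
  }
  K <- length(draws$subsets)
  mean(rowSums(draws$theta) - K * draws$theta_global > c2)
}
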