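# Enrichment decision rules.
#
# At each analysis the design enriches toward subset k (stops enrolling the
# others) when both conditions hold in k:
#   influence:   P_1k = P(theta_k < lambda | Data)            >  gamma
#   interaction: (Millen)      P_2k                            >  tau
#                (Gail-Simon)  P_quali and/or P_quanti         >  epsilon
# Otherwise the trial continues in the entire population.  All inequalities
# are strict.  With K > 2 several subsets can qualify simultaneously and the
# trial is enriched by all of them at once.

#' Decision thresholds
#'
#' Bundles every cutoff of the enrichment decision rules.  None of the
#' calibratable thresholds has a hard-coded default: `gamma` (and `tau`,
#' `epsilon`, `c1`, `c2` as the rule requires) must come from
#' [calibrate_thresholds()] or from a design configuration.  Only the
#' minimal effect size `lam` is a fixed design input (default 0.9).
#'
#' @param gamma influence cutoff, in `(0, 1]`.
#' @param lam minimal effect size lambda for the influence condition
#'   (default 0.9).
#' @param eta minimal interaction ratio for Millen's criterion, `>= 1`.
#' @param tau Millen interaction cutoff, in `(0, 1]`.
#' @param epsilon Gail-Simon interaction cutoff, in `(0, 1]`.
#' @param c1 qualitative-statistic cutoff C1, `>= 0`.
#' @param c2 quantitative-statistic cutoff C2.
#' @param rule `"millen"` or `"gail_simon"`.
#' @param gs_mode which Gail-Simon probabilities may establish interaction:
#'   `"either"` (default; qualitative or quantitative), `"quali"`,
#'   `"quanti"`, or `"both"` (both must exceed `epsilon`).
#' @return An object of class `enrich_thresholds`.
#' @examples
#' enrich_thresholds(gamma = 0.9, eta = 1, tau = 0.9, rule = "millen")
#' @export
enrich_thresholds <- function(gamma, lam = 0.9, eta = NULL, tau = NULL,
                              epsilon = NULL, c1 = NULL, c2 = NULL,
                              rule = c("millen", "gail_simon"),
                              gs_mode = c("either", "quali", "quanti", "both")) {
  rule <- match.arg(rule)
  gs_mode <- match.arg(gs_mode)
  .assert_prob(gamma, "gamma", open0 = TRUE)
  if (!is.numeric(lam) || lam <= 0) stop("'lam' must be > 0", call. = FALSE)
  if (rule == "millen") {
    if (is.null(eta) || is.null(tau)) {
      stop("Millen's rule requires 'eta' and 'tau'", call. = FALSE)
    }
    if (eta < 1) stop("'eta' must be >= 1", call. = FALSE)
    .assert_prob(tau, "tau", open0 = TRUE)
  } else {
    if (is.null(epsilon)) {
      stop("the Gail-Simon rule requires 'epsilon'", call. = FALSE)
    }
    .assert_prob(epsilon, "epsilon", open0 = TRUE)
    need_c1 <- gs_mode %in% c("either", "both", "quali")
    need_c2 <- gs_mode %in% c("either", "both", "quanti")
    if (need_c1 && is.null(c1)) stop("gs_mode needs 'c1'", call. = FALSE)
    if (need_c2 && is.null(c2)) stop("gs_mode needs 'c2'", call. = FALSE)
    if (!is.null(c1) && c1 < 0) stop("'c1' must be >= 0", call. = FALSE)
  }
  structure(list(lam = lam, gamma = gamma, eta = eta, tau = tau,
                 epsilon = epsilon, c1 = c1, c2 = c2, rule = rule,
                 gs_mode = gs_mode),
            class = "enrich_thresholds")
}

#' @export
print.enrich_thresholds <- function(x, ...) {
  cat(sprintf("Enrichment thresholds (%s rule):\n", x$rule))
  cat(sprintf("  influence: lambda = %g, gamma = %g\n", x$lam, x$gamma))
  if (x$rule == "millen") {
    cat(sprintf("  interaction: eta = %g, tau = %g\n", x$eta, x$tau))
  } else {
    cat(sprintf("  interaction (%s): epsilon = %g, C1 = %s, C2 = %s\n",
                x$gs_mode, x$epsilon,
                if (is.null(x$c1)) "-" else format(x$c1),
                if (is.null(x$c2)) "-" else format(x$c2)))
  }
  invisible(x)
}

# Interaction-met flag from a pair of Gail-Simon probabilities.
.gs_met <- function(p_quali, p_quanti, epsilon, gs_mode) {
  switch(gs_mode,
         quali  = p_quali > epsilon,
         quanti = p_quanti > epsilon,
         either = p_quali > epsilon | p_quanti > epsilon,
         both   = p_quali > epsilon & p_quanti > epsilon)
}

#' Evaluate the enrichment decision rules at one analysis
#'
#' Samples the joint posterior from the current counts (restricted to the
#' active subsets), computes the influence probability of every active
#' subset and the interaction criterion of the selected rule, and applies
#' the decision rules: a subset joins the enrichment set iff its influence
#' condition and the interaction condition both hold; if none qualifies the
#' trial continues in the entire (active) population.
#'
#' With Millen's rule (K = 2), should both subsets qualify the tie is broken
#' toward the larger influence probability, so replications stay
#' deterministic.  With a single active subset no interaction is evaluable
#' and the analysis reports estimates only.
#'
#' @param counts [subset_arm_counts()] restricted to the active subsets.
#' @param active_subsets character vector of currently active subset labels.
#' @param thresholds an [enrich_thresholds()] object.
#' @param prior Beta prior (default `beta_params(1, 1)`).
#' @param n_draws Monte-Carlo draws per analysis.
#' @param seed integer seed for the posterior draws.
#' @param global_method passed to [sample_posterior()].
#' @return An object of class `enrich_decision`: a list with `action`
#'   (`"continue_entire_population"` or `"enrich"`), `enriched_subsets`,
#'   `evidence` (one row per active subset: `P1`, `P2`,
#'   `conditioning_fraction`, `P_quali`, `P_quanti`, `influence_met`,
#'   `interaction_met`, `qualifies`) and `estimates`
#'   (from [posterior_estimates()]).
#' @export
evaluate_analysis <- function(counts, active_subsets, thresholds,
                              prior = beta_params(1, 1), n_draws = 10000,
                              seed = 1L,
                              global_method = c("pooled", "weighted")) {
  stopifnot(inherits(counts, "subset_arm_counts"),
            inherits(thresholds, "enrich_thresholds"))
  if (length(active_subsets) < 1L) stop("no active subsets", call. = FALSE)
  if (!all(active_subsets %in% counts$subsets)) {
    stop("counts must cover every active subset", call. = FALSE)
  }
  counts <- restrict_counts(counts, active_subsets)
  if (sum(counts$totals) == 0) stop("empty counts", call. = FALSE)
  draws <- sample_posterior(counts, prior, n_draws, seed,
                            global_method = match.arg(global_method))
  K <- length(active_subsets)
  p1k <- vapply(active_subsets, function(k)
    influence_probability(draws, k, thresholds$lam), numeric(1))
  ev <- data.frame(subset = active_subsets, P1 = p1k,
                   P2 = NA_real_, conditioning_fraction = NA_real_,
                   P_quali = NA_real_, P_quanti = NA_real_,
                   influence_met = p1k > thresholds$gamma,
                   interaction_met = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  if (K >= 2L) {
    if (thresholds$rule == "millen") {
      if (K != 2L) {
        stop("Millen's rule applies only to K = 2 active subsets; ",
             "use the Gail-Simon rule for K > 2", call. = FALSE)
      }
      for (i in 1:2) {
        other <- active_subsets[3 - i]
        # an empty conditioning event is reported through
        # conditioning_fraction = 0, so the warning is redundant here
        m <- suppressWarnings(
          millen_probability(draws, active_subsets[i], other, thresholds$eta))
        ev$P2[i] <- m$probability
        ev$conditioning_fraction[i] <- m$conditioning_fraction
      }
      ev$interaction_met <- ev$P2 > thresholds$tau
    } else {
      gs <- gail_simon_draws(draws)
      pq <- if (thresholds$gs_mode %in% c("either", "both", "quali"))
        quali_probability(gs, thresholds$c1) else NA_real_
      pt <- if (thresholds$gs_mode %in% c("either", "both", "quanti"))
        quanti_probability(draws, thresholds$c2) else NA_real_
      ev$P_quali <- pq
      ev$P_quanti <- pt
      ev$interaction_met <- .gs_met(ifelse(is.na(pq), -Inf, pq),
                                    ifelse(is.na(pt), -Inf, pt),
                                    thresholds$epsilon, thresholds$gs_mode)
    }
  }
  ev$qualifies <- ev$influence_met & ev$interaction_met
  enriched <- ev$subset[ev$qualifies]
  if (thresholds$rule == "millen" && length(enriched) == 2L) {
    keep <- which.max(ev$P1)
    message("both subsets qualify under Millen's rule; tie broken toward ",
            ev$subset[keep], " (larger influence probability)")
    enriched <- ev$subset[keep]
  }
  structure(list(action = if (length(enriched)) "enrich"
                 else "continue_entire_population",
                 enriched_subsets = enriched,
                 evidence = ev,
                 estimates = posterior_estimates(draws)),
            class = "enrich_decision")
}

#' @export
print.enrich_decision <- function(x, ...) {
  cat("Decision:", if (x$action == "enrich")
    paste("enrich", paste(x$enriched_subsets, collapse = " + "))
    else "continue with the entire population", "\n")
  print(x$evidence, digits = 3)
  invisible(x)
}

#' Advance the enrichment state after a decision
#'
#' If the decision enriches, the active set shrinks to the enriched subsets
#' and the state is frozen for interaction: subsequent analyses only update
#' estimates, with no further rule evaluation (matching a design in which
#' enrichment is permanent).  Otherwise the state is unchanged.
#'
#' @param state list with `active` (character vector) and `frozen` (flag);
#'   a plain character vector is promoted to an unfrozen state.
#' @param decision an `enrich_decision`.
#' @return The updated state list.
#' @export
update_enrichment_state <- function(state, decision) {
  if (is.character(state)) state <- list(active = state, frozen = FALSE)
  stopifnot(inherits(decision, "enrich_decision"))
  if (decision$action == "enrich") {
    if (!all(decision$enriched_subsets %in% state$active)) {
      stop("enriched subsets must be among the active subsets", call. = FALSE)
    }
    state$active <- decision$enriched_subsets
    state$frozen <- TRUE
  }
  state
}
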