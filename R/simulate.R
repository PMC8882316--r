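# Patient-level trial simulator with enrichment-aware accrual.
#
# A trial enrolls n_total patients in n_analyses equal blocks; at the end of
# each block an analysis applies the decision rules.  On enrichment, accrual
# is restricted to the enriched subsets (prevalence renormalized over the
# active subsets, so dropped-subset slots are refilled and total accrual
# always reaches n_total) and the rules are frozen: later analyses only
# update estimates.  All already-enrolled patients — including those from
# dropped subsets — contribute to the terminal estimates.
#
# Randomness is organised in reproducible sub-streams derived from a master
# seed: stream 1 = accrual per analysis block, stream 2 = posterior draws
# per analysis, stream 3 = per-replication master seeds.

.STREAM_ACCRUAL <- 1L
.STREAM_DRAWS <- 2L
.STREAM_REPLICATION <- 3L

#' Simulate patient enrollment
#'
#' Draws `n` patients under a scenario truth with accrual restricted to the
#' active subsets: the subset label is drawn from the prevalences
#' renormalized over `active_subsets`, the arm is Bernoulli(q_k) and the
#' outcome Bernoulli(p_jk).  Enrollment is uniform over the accrual period,
#' so patient order carries no further structure.
#'
#' @param scenario an [scenario()] object.
#' @param n number of patients to enroll.
#' @param active_subsets labels open to accrual (default all).
#' @param seed integer seed.
#' @return A data frame with columns `subset`, `arm`, `outcome`.
#' @export
generate_patients <- function(scenario, n, active_subsets = scenario$subsets,
                              seed = 1L) {
  stopifnot(inherits(scenario, "enrich_scenario"))
  if (!length(active_subsets) || !all(active_subsets %in% scenario$subsets)) {
    stop("'active_subsets' must be a nonempty subset of the scenario's labels",
         call. = FALSE)
  }
  w <- scenario$pi[active_subsets]
  if (sum(w) <= 0) stop("restricted prevalence is all zero", call. = FALSE)
  set.seed(as.integer(seed))
  subset <- if (length(active_subsets) == 1L) rep(active_subsets, n)
            else sample(active_subsets, n, replace = TRUE, prob = w / sum(w))
  arm <- stats::rbinom(n, 1L, scenario$q[subset])
  p <- ifelse(arm == 1L, scenario$p1[subset], scenario$p0[subset])
  data.frame(subset = subset, arm = arm, outcome = stats::rbinom(n, 1L, p),
             stringsAsFactors = FALSE)
}

#' Simulate a single patient
#'
#' Convenience wrapper around [generate_patients()] for one enrollment.
#'
#' @inheritParams generate_patients
#' @return A one-row data frame with columns `subset`, `arm`, `outcome`.
#' @export
generate_patient <- function(scenario, active_subsets = scenario$subsets,
                             seed = 1L) {
  generate_patients(scenario, 1L, active_subsets, seed)
}

#' Run one adaptive enrichment trial
#'
#' Enrolls to each analysis boundary, applies the decision rules via
#' [evaluate_analysis()], restricts accrual on enrichment (rules frozen
#' thereafter), and computes terminal posterior estimates of every subset
#' relative risk and the global effect from all enrolled patients.
#' The terminal analysis applies the rules too (if still unfrozen), so the
#' terminal classification is either the entire population or the enriched
#' subset set.
#'
#' @param scenario an [scenario()] object.
#' @param thresholds an [enrich_thresholds()] object.
#' @param n_total total sample size (default 800); must split into
#'   `n_analyses` equal blocks.
#' @param n_analyses number of analyses including the terminal one
#'   (default 4: three interim plus terminal, every `n_total / 4` patients).
#' @param prior Beta prior (default `beta_params(1, 1)`).
#' @param n_draws posterior draws per analysis.
#' @param master_seed integer master seed for this replication.
#' @param re_evaluate_after_enrichment if `TRUE` and more than one subset
#'   remains active after an enrichment, later analyses may narrow the
#'   active set further (default `FALSE`: first enrichment is final).
#' @param keep_patients keep the simulated patient-level records in the
#'   result (default `FALSE`).
#' @param global_method passed to [sample_posterior()].
#' @return An object of class `trial_result`: `final_action`
#'   (classification label), `enriched_subsets`, `enrichment_look`,
#'   `decisions` (per-look list of `enrich_decision` or `NULL` once
#'   frozen), `looks` (per-look data frame: cumulative per-subset counts,
#'   enriched flag), `n_k` (terminal per-subset totals), `estimates`
#'   (posterior means and 95% credibility intervals), `seed`, and
#'   optionally `patients`.
#' @export
run_trial <- function(scenario, thresholds, n_total = 800, n_analyses = 4,
                      prior = beta_params(1, 1), n_draws = 10000,
                      master_seed = 1L,
                      re_evaluate_after_enrichment = FALSE,
                      keep_patients = FALSE,
                      global_method = c("pooled", "weighted")) {
  stopifnot(inherits(scenario, "enrich_scenario"),
            inherits(thresholds, "enrich_thresholds"))
  global_method <- match.arg(global_method)
  if (n_analyses < 1 || n_total %% n_analyses != 0) {
    stop("'n_total' must divide into 'n_analyses' equal analysis blocks",
         call. = FALSE)
  }
  block <- n_total %/% n_analyses
  subsets <- scenario$subsets
  state <- list(active = subsets, frozen = FALSE)
  patients <- vector("list", n_analyses)
  decisions <- vector("list", n_analyses)
  cum_n <- matrix(0L, n_analyses, scenario$K,
                  dimnames = list(NULL, subsets))
  enriched_flag <- logical(n_analyses)
  enrichment_look <- NA_integer_
  counts <- NULL
  for (a in seq_len(n_analyses)) {
    patients[[a]] <- generate_patients(
      scenario, block, state$active,
      seed = derive_seed(master_seed, .STREAM_ACCRUAL, a))
    all_pat <- do.call(rbind, patients[seq_len(a)])
    counts <- count_records(all_pat, subsets)
    cum_n[a, ] <- colSums(counts$totals)
    evaluable <- !state$frozen && length(state$active) >= 2L
    if (evaluable) {
      dec <- evaluate_analysis(counts, state$active, thresholds, prior,
                               n_draws,
                               seed = derive_seed(master_seed, .STREAM_DRAWS, a),
                               global_method = global_method)
      decisions[[a]] <- dec
      if (dec$action == "enrich") {
        state <- update_enrichment_state(state, dec)
        if (re_evaluate_after_enrichment && length(state$active) >= 2L) {
          state$frozen <- FALSE
        }
        if (is.na(enrichment_look)) enrichment_look <- a
      }
    }
    enriched_flag[a] <- !is.na(enrichment_look)
  }
  final_draws <- sample_posterior(
    counts, prior, n_draws,
    seed = derive_seed(master_seed, .STREAM_DRAWS, n_analyses + 1L),
    global_method = global_method)
  enriched <- if (is.na(enrichment_look)) character(0) else state$active
  res <- list(final_action = classification_label(enriched),
              enriched_subsets = enriched,
              enrichment_look = enrichment_look,
              decisions = decisions,
              looks = data.frame(look = seq_len(n_analyses), cum_n,
                                 enriched = enriched_flag),
              cum_n = cum_n,
              n_k = stats::setNames(cum_n[n_analyses, ], subsets),
              estimates = posterior_estimates(final_draws),
              scenario_label = scenario$label,
              n_total = n_total, n_analyses = n_analyses,
              seed = as.integer(master_seed))
  if (keep_patients) res$patients <- do.call(rbind, patients)
  structure(res, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial result (%s): %s%s\n", x$scenario_label,
              if (x$final_action == "entire_population")
                "go with the entire population"
              else paste("enriched in", x$final_action),
              if (!is.na(x$enrichment_look))
                sprintf(" (enriched at analysis %d)", x$enrichment_look)
              else ""))
  cat("Terminal sample sizes:",
      paste(sprintf("%s=%d", names(x$n_k), x$n_k), collapse = "  "), "\n")
  print(x$estimates, digits = 3)
  invisible(x)
}

# All admissible terminal classifications: the entire population plus every
# nonempty subset of the biomarker subsets (single subsets, pairs for K = 3,
# ...; under the Gail-Simon rule every subset can qualify at once, so the
# full set is admissible too and distinct from never having enriched).
classification_levels <- function(subsets) {
  K <- length(subsets)
  sets <- unlist(lapply(seq_len(K), function(m)
    utils::combn(subsets, m, function(s) paste(sort(s), collapse = "+"),
                 simplify = TRUE)), use.names = FALSE)
  c("entire_population", sets)
}

#' Replicate trials and aggregate operating characteristics
#'
#' Runs `N` independent replications of [run_trial()] (replication r uses a
#' seed derived from `(master_seed, r)`) and aggregates decision
#' proportions, mean per-subset sample sizes, estimation bias, the
#' design-level false positive rate and (for non-null scenarios) the power.
#'
#' The false positive rate is the proportion of replications enriching any
#' subset under a null scenario; under a non-null scenario it is the
#' proportion of replications whose enrichment includes a subset with no
#' true benefit.  Power is the proportion of replications ending enriched
#' within the truly sensitive subsets (`theta_k < 1`); enrichment of a
#' wrong subset counts against power, not toward it.
#'
#' @inheritParams run_trial
#' @param N number of replications.
#' @param cores serial execution when 1 (default); with more cores
#'   replications run via [parallel::mclapply()] with results identical to
#'   serial execution (seeds are per-replication).
#' @param keep_results keep the full list of `trial_result`s.
#' @return An object of class `operating_characteristics`:
#'   `decision_proportions` (named, over the exhaustive classification set,
#'   summing to 1), `mean_n_k`, `mean_bias_theta_k`,
#'   `false_positive_rate`, `power`, per-look `look_enriched_prop` and
#'   `look_mean_cum_n`, `N`, plus the scenario and thresholds used.
#' @export
replicate_trials <- function(scenario, thresholds, n_total = 800,
                             n_analyses = 4, prior = beta_params(1, 1),
                             n_draws = 10000, N = 1000, master_seed = 1L,
                             cores = 1L,
                             re_evaluate_after_enrichment = FALSE,
                             keep_results = FALSE,
                             global_method = c("pooled", "weighted")) {
  stopifnot(N >= 1)
  global_method <- match.arg(global_method)
  one <- function(r) {
    run_trial(scenario, thresholds, n_total, n_analyses, prior, n_draws,
              master_seed = derive_seed(master_seed, .STREAM_REPLICATION, r),
              re_evaluate_after_enrichment = re_evaluate_after_enrichment,
              global_method = global_method)
  }
  results <- if (cores > 1L) {
    parallel::mclapply(seq_len(N), one, mc.cores = cores)
  } else {
    lapply(seq_len(N), one)
  }
  summarize_replications(results, scenario, thresholds, n_total, n_analyses,
                         keep_results)
}

# Aggregate a list of trial_result objects into operating characteristics.
summarize_replications <- function(results, scenario, thresholds, n_total,
                                   n_analyses, keep_results = FALSE) {
  N <- length(results)
  subsets <- scenario$subsets
  levels <- classification_levels(subsets)
  cls <- vapply(results, `[[`, character(1), "final_action")
  prop <- table(factor(cls, levels = levels)) / N
  n_k <- t(vapply(results, `[[`, numeric(scenario$K), "n_k"))
  theta_hat <- t(vapply(results, function(r)
    r$estimates$theta_hat[match(subsets, r$estimates$subset)],
    numeric(scenario$K)))
  enriched_sets <- lapply(results, `[[`, "enriched_subsets")
  false_pos <- vapply(enriched_sets, function(s) {
    length(s) > 0 && (scenario$null || any(!s %in% scenario$sensitive))
  }, logical(1))
  power <- if (length(scenario$sensitive)) {
    mean(vapply(enriched_sets, function(s)
      length(s) > 0 && all(s %in% scenario$sensitive), logical(1)))
  } else NA_real_
  look_enriched <- t(vapply(results, function(r) r$looks$enriched,
                            logical(n_analyses)))
  look_cum_n <- Reduce(`+`, lapply(results, `[[`, "cum_n")) / N
  structure(list(decision_proportions = stats::setNames(as.numeric(prop),
                                                        levels),
                 mean_n_k = stats::setNames(colMeans(n_k), subsets),
                 mean_bias_theta_k = stats::setNames(
                   colMeans(theta_hat) - scenario$theta, subsets),
                 false_positive_rate = mean(false_pos),
                 power = power,
                 look_enriched_prop = colMeans(look_enriched),
                 look_mean_cum_n = look_cum_n,
                 N = N, n_total = n_total, n_analyses = n_analyses,
                 scenario = scenario, thresholds = thresholds,
                 results = if (keep_results) results else NULL),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics over N = %d replications (%s):\n",
              x$N, x$scenario$label))
  nz <- x$decision_proportions[x$decision_proportions > 0 |
                                 names(x$decision_proportions) ==
                                 "entire_population"]
  for (nm in names(nz)) cat(sprintf("  %-22s %.4f\n", nm, nz[nm]))
  cat("Mean sample sizes:",
      paste(sprintf("%s=%.1f", names(x$mean_n_k), x$mean_n_k),
            collapse = "  "), "\n")
  cat(sprintf("False positive rate: %.4f", x$false_positive_rate))
  if (!is.na(x$power)) cat(sprintf("   Power: %.4f", x$power))
  cat("\n")
  invisible(x)
}
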