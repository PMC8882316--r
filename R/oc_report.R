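# Tabulation of operating characteristics: end-of-trial decision tables,
# per-look decision trajectories, and prevalence / allocation sensitivity
# sweeps.  Tables are the canonical output; plots are optional artifacts
# derived from them.

#' Tabulate end-of-trial decision proportions
#'
#' One row per operating-characteristics object (scenario x rule) with the
#' proportion of replications continuing in the entire population, the
#' per-subset (and, for K = 3, per-pair) enrichment proportions, the mean
#' per-subset sample sizes and the false positive rate.  Proportions over
#' the exhaustive outcome set sum to 1.
#'
#' @param ocs a single [replicate_trials()] result or a (preferably named)
#'   list of them; all must share the same total sample size and analysis
#'   schedule.
#' @param rule_labels optional character vector labelling each row's rule.
#' @return A data frame.
#' @export
tabulate_decisions <- function(ocs, rule_labels = NULL) {
  if (inherits(ocs, "operating_characteristics")) ocs <- list(ocs)
  stopifnot(all(vapply(ocs, inherits, logical(1),
                       "operating_characteristics")))
  n_tot <- vapply(ocs, `[[`, numeric(1), "n_total")
  n_an <- vapply(ocs, `[[`, numeric(1), "n_analyses")
  if (length(unique(n_tot)) != 1L || length(unique(n_an)) != 1L) {
    stop("all operating characteristics must share n_total and the schedule",
         call. = FALSE)
  }
  rows <- lapply(seq_along(ocs), function(i) {
    oc <- ocs[[i]]
    dp <- oc$decision_proportions
    row <- data.frame(
      scenario = if (nzchar(oc$scenario$label)) oc$scenario$label
                 else paste0("scenario", i),
      rule = if (!is.null(rule_labels)) rule_labels[i]
             else oc$thresholds$rule,
      go_entire_population = dp[["entire_population"]],
      stringsAsFactors = FALSE)
    for (nm in setdiff(names(dp), "entire_population")) {
      row[[paste0("enrich_", gsub("\\+", "_", nm))]] <- dp[[nm]]
    }
    for (k in names(oc$mean_n_k)) row[[paste0("n_", k)]] <- oc$mean_n_k[[k]]
    row$false_positive <- oc$false_positive_rate
    row
  })
  do.call(rbind, rows)
}

#' Per-look decision trajectory
#'
#' For each analysis (interim analyses IA1, IA2, ... and the terminal
#' analysis TA): the proportion of replications already enriched, the
#' proportion still continuing in the entire population, and the mean
#' cumulative per-subset sample sizes.
#'
#' @param x a [replicate_trials()] result, or a list of
#'   [run_trial()] results.
#' @return A data frame with one row per analysis.
#' @export
trajectory_table <- function(x) {
  if (inherits(x, "operating_characteristics")) {
    enr <- x$look_enriched_prop
    cum <- x$look_mean_cum_n
    L <- x$n_analyses
  } else {
    stopifnot(length(x) > 0,
              all(vapply(x, inherits, logical(1), "trial_result")))
    L <- x[[1]]$n_analyses
    enr <- colMeans(t(vapply(x, function(r) r$looks$enriched, logical(L))))
    cum <- Reduce(`+`, lapply(x, `[[`, "cum_n")) / length(x)
  }
  out <- data.frame(look = seq_len(L),
                    analysis = c(paste0("IA", seq_len(L - 1L)), "TA"),
                    prop_enriched = enr, prop_continuing = 1 - enr,
                    stringsAsFactors = FALSE)
  for (k in colnames(cum)) out[[paste0("cum_n_", k)]] <- cum[, k]
  out
}

#' Prevalence or allocation sensitivity sweep
#'
#' Re-runs the operating characteristics of a base scenario across a range
#' of subset-A prevalences or experimental-arm allocation probabilities.
#' For allocation sweeps (K = 2) the subset-B allocation is derived so the
#' trial stays 1:1 overall ([balanced_q_B()]).  Every sweep value reuses the
#' same master seed, so a sweep at the base value reproduces the base
#' operating characteristics bitwise.
#'
#' @param base_scenario the [scenario()] to perturb.
#' @param vary `"prevalence"` or `"allocation"`.
#' @param values for `"prevalence"`: subset-A prevalences (K = 2), or a
#'   list of length-K prevalence vectors; for `"allocation"`: subset-A
#'   allocation probabilities q_A (K = 2 only).
#' @param thresholds an [enrich_thresholds()] object.
#' @inheritParams replicate_trials
#' @return An object of class `sweep_result`: `table` (one
#'   [tabulate_decisions()] row per value, with a leading `value` column)
#'   and `ocs` (the underlying operating characteristics).
#' @export
run_sweep <- function(base_scenario, vary = c("prevalence", "allocation"),
                      values, thresholds, N = 1000, master_seed = 1L,
                      n_total = 800, n_analyses = 4,
                      prior = beta_params(1, 1), n_draws = 10000,
                      cores = 1L) {
  vary <- match.arg(vary)
  stopifnot(inherits(base_scenario, "enrich_scenario"))
  scenarios <- lapply(values, function(v) {
    sc <- base_scenario
    if (vary == "prevalence") {
      if (length(v) == 1L) {
        if (sc$K != 2L) {
          stop("scalar prevalence sweep values require K = 2; supply full ",
               "prevalence vectors for K > 2", call. = FALSE)
        }
        .assert_prob(v, "prevalence", open0 = TRUE, open1 = TRUE)
        pi <- stats::setNames(c(v, 1 - v), sc$subsets)
      } else {
        if (length(v) != sc$K) {
          stop("prevalence vector length must equal K", call. = FALSE)
        }
        pi <- stats::setNames(as.numeric(v), sc$subsets)
      }
      scenario(sc$p1, sc$p0, pi = pi, q = sc$q, label = sc$label,
               null = sc$null)
    } else {
      if (sc$K != 2L) {
        stop("allocation sweeps are defined for K = 2", call. = FALSE)
      }
      .assert_prob(v, "q_A", open0 = TRUE, open1 = TRUE)
      q <- stats::setNames(c(v, balanced_q_B(v, sc$pi[1])), sc$subsets)
      scenario(sc$p1, sc$p0, pi = sc$pi, q = q, label = sc$label,
               null = sc$null)
    }
  })
  ocs <- lapply(scenarios, function(sc) {
    replicate_trials(sc, thresholds, n_total, n_analyses, prior, n_draws,
                     N = N, master_seed = master_seed, cores = cores)
  })
  value_label <- vapply(values, function(v)
    paste(format(v, digits = 4), collapse = "/"), character(1))
  tab <- tabulate_decisions(ocs)
  tab <- cbind(data.frame(value = value_label, stringsAsFactors = FALSE), tab)
  structure(list(table = tab, ocs = ocs, vary = vary, values = values),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sensitivity sweep over %s (%d values):\n", x$vary,
              length(x$values)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Plot a decision trajectory or sweep table
#'
#' Simple ggplot2 renderings of [trajectory_table()] and
#' [run_sweep()] outputs; requires ggplot2.
#'
#' @param x a `sweep_result` or the output of [trajectory_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (inherits(x, "sweep_result")) {
    df <- x$table
    df$value_num <- vapply(x$values, function(v) as.numeric(v[1]), numeric(1))
    ggplot2::ggplot(df, ggplot2::aes(x = value_num, y = 1 - go_entire_population)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = x$vary, y = "proportion enriched") +
      ggplot2::ylim(0, 1)
  } else {
    ggplot2::ggplot(x, ggplot2::aes(x = look, y = prop_enriched)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "analysis", y = "proportion enriched") +
      ggplot2::ylim(0, 1)
  }
}
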