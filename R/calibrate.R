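# Grid-search calibration of the decision thresholds.
#
# The calibration exploits a structural property of the design: because the
# first enrichment freezes rule evaluation, a replication's terminal
# classification is fully determined by its pre-enrichment probability
# trajectory (the per-analysis influence and interaction probabilities
# computed on unrestricted accrual).  Those trajectories are simulated once
# per replication — common random numbers across all grid points — and every
# candidate threshold vector is then evaluated by pure thresholding, making
# the grid comparison low-variance and the argmax stable.

#' Default threshold grids
#'
#' Candidate values for the grid search, centered on 0.90 for the
#' probability cutoffs and spanning plausible ranges for the interaction
#' statistics' cutoffs.  All overridable in [calibration_spec()].
#'
#' @return Named list of candidate vectors for `gamma`, `tau`, `epsilon`,
#'   `eta`, `c1`, `c2`.
#' @export
default_grids <- function() {
  list(gamma = c(0.80, 0.85, 0.90, 0.95),
       tau = c(0.80, 0.85, 0.90, 0.95),
       epsilon = c(0.05, 0.10, 0.25, 0.50, 0.80, 0.85, 0.90, 0.95),
       eta = c(1.0, 1.1, 1.25, 1.5),
       c1 = c(0.5, 1, 2, 3, 4, 6),
       c2 = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1))
}

#' Specify a threshold calibration
#'
#' @param null_scenario the null [scenario()] under which the false positive
#'   rate (probability of any enrichment) is controlled.
#' @param power_scenarios list of effect [scenario()]s over which enrichment
#'   power is averaged and maximized.
#' @param grid named list of candidate values per threshold; missing entries
#'   fall back to [default_grids()].
#' @param alpha_target nominal false-positive bound (default 0.05).
#' @param N_cal replications used per grid point (default 500).
#' @param n_total,n_analyses trial schedule (defaults 800 patients, 4
#'   analyses).
#' @param prior Beta prior.
#' @param n_draws posterior draws per analysis during calibration.
#' @param lam minimal effect size lambda — fixed design input, not
#'   calibrated (default 0.9).
#' @param seed master seed.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(null_scenario, power_scenarios,
                             grid = list(), alpha_target = 0.05,
                             N_cal = 500, n_total = 800, n_analyses = 4,
                             prior = beta_params(1, 1), n_draws = 2000,
                             lam = 0.9, seed = 1L) {
  stopifnot(inherits(null_scenario, "enrich_scenario"))
  if (inherits(power_scenarios, "enrich_scenario")) {
    power_scenarios <- list(power_scenarios)
  }
  if (!length(power_scenarios) ||
      !all(vapply(power_scenarios, inherits, logical(1), "enrich_scenario"))) {
    stop("'power_scenarios' must be a nonempty list of scenarios",
         call. = FALSE)
  }
  .assert_prob(alpha_target, "alpha_target", open0 = TRUE, open1 = TRUE)
  grid <- utils::modifyList(default_grids(), grid)
  if (any(!vapply(grid, length, integer(1)))) {
    stop("all grids must be nonempty", call. = FALSE)
  }
  structure(list(null_scenario = null_scenario,
                 power_scenarios = power_scenarios, grid = grid,
                 alpha_target = alpha_target, N_cal = N_cal,
                 n_total = n_total, n_analyses = n_analyses, prior = prior,
                 n_draws = n_draws, lam = lam, seed = as.integer(seed)),
            class = "calibration_spec")
}

#' Simulate pre-enrichment decision-probability trajectories
#'
#' For `N` replications, simulates the full unrestricted accrual of a trial
#' and records, at every analysis, the influence probability of each subset
#' and the interaction probabilities evaluated at each candidate cutoff
#' (`eta` for Millen; `c1`/`c2` for Gail-Simon).  Replication r uses the
#' same derived seeds as [replicate_trials()], so thresholding these
#' trajectories reproduces the simulator's decisions exactly.
#'
#' @inheritParams run_trial
#' @param N number of replications.
#' @param eta_grid,c1_grid,c2_grid candidate cutoffs at which the
#'   interaction probabilities are tabulated.
#' @param lam minimal effect size for the influence probabilities.
#' @return An object of class `decision_paths` holding arrays
#'   `P1[rep, look, subset]`, `P2[rep, look, subset, eta]` (K = 2 only),
#'   `P_quali[rep, look, c1]`, `P_quanti[rep, look, c2]`.
#' @export
simulate_decision_paths <- function(scenario, n_total = 800, n_analyses = 4,
                                    prior = beta_params(1, 1),
                                    n_draws = 2000, N = 500,
                                    master_seed = 1L, lam = 0.9,
                                    eta_grid = default_grids()$eta,
                                    c1_grid = default_grids()$c1,
                                    c2_grid = default_grids()$c2,
                                    global_method = c("pooled", "weighted")) {
  stopifnot(inherits(scenario, "enrich_scenario"))
  global_method <- match.arg(global_method)
  block <- n_total %/% n_analyses
  if (n_total %% n_analyses != 0) {
    stop("'n_total' must divide into equal analysis blocks", call. = FALSE)
  }
  K <- scenario$K
  subsets <- scenario$subsets
  L <- n_analyses
  P1 <- array(NA_real_, c(N, L, K), dimnames = list(NULL, NULL, subsets))
  P2 <- if (K == 2L) {
    array(NA_real_, c(N, L, K, length(eta_grid)),
          dimnames = list(NULL, NULL, subsets, NULL))
  } else NULL
  Pquali <- array(NA_real_, c(N, L, length(c1_grid)))
  Pquanti <- array(NA_real_, c(N, L, length(c2_grid)))
  for (r in seq_len(N)) {
    rep_seed <- derive_seed(master_seed, .STREAM_REPLICATION, r)
    records <- NULL
    for (a in seq_len(L)) {
      blk <- generate_patients(scenario, block, subsets,
                               seed = derive_seed(rep_seed, .STREAM_ACCRUAL, a))
      records <- if (is.null(records)) blk else rbind(records, blk)
      counts <- count_records(records, subsets)
      draws <- sample_posterior(counts, prior, n_draws,
                                seed = derive_seed(rep_seed, .STREAM_DRAWS, a),
                                global_method = global_method)
      P1[r, a, ] <- colMeans(draws$theta < lam)
      if (K == 2L) {
        for (i in 1:2) {
          tk <- draws$theta[, i]; tt <- draws$theta[, 3 - i]
          cond <- tt >= tk
          if (any(cond)) {
            ratio <- tt[cond] / tk[cond]
            P2[r, a, i, ] <- vapply(eta_grid, function(e) mean(ratio > e),
                                    numeric(1))
          } else P2[r, a, i, ] <- 0
        }
      }
      gs <- gail_simon_draws(draws)
      minq <- pmin(gs$q_minus, gs$q_plus)
      Pquali[r, a, ] <- vapply(c1_grid, function(c1) mean(minq > c1),
                               numeric(1))
      s <- rowSums(draws$theta) - K * draws$theta_global
      Pquanti[r, a, ] <- vapply(c2_grid, function(c2) mean(s > c2),
                                numeric(1))
    }
  }
  structure(list(P1 = P1, P2 = P2, P_quali = Pquali, P_quanti = Pquanti,
                 subsets = subsets, n_analyses = L, N = N,
                 eta_grid = eta_grid, c1_grid = c1_grid, c2_grid = c2_grid,
                 lam = lam, master_seed = as.integer(master_seed)),
            class = "decision_paths")
}

#' Classify replications from stored decision-probability trajectories
#'
#' Applies a threshold vector to [simulate_decision_paths()] output: each
#' replication is classified by the first analysis at which a subset meets
#' both the influence and interaction conditions (rules frozen thereafter),
#' reproducing [run_trial()]'s terminal classification under the same
#' seeds.
#'
#' @param paths a `decision_paths` object.
#' @param thresholds an [enrich_thresholds()] object whose `eta` (Millen)
#'   or `c1`/`c2` (Gail-Simon) values appear in the path's tabulated grids.
#' @return A list with `classification` (character per replication) and
#'   `enrichment_look` (integer or `NA` per replication).
#' @export
classify_paths <- function(paths, thresholds) {
  stopifnot(inherits(paths, "decision_paths"),
            inherits(thresholds, "enrich_thresholds"))
  N <- paths$N; L <- paths$n_analyses
  subsets <- paths$subsets; K <- length(subsets)
  if (thresholds$rule == "millen") {
    if (is.null(paths$P2)) {
      stop("Millen classification needs K = 2 decision paths", call. = FALSE)
    }
    ei <- match(thresholds$eta, paths$eta_grid)
    if (is.na(ei)) stop("'eta' not tabulated in these paths", call. = FALSE)
    p2 <- array(paths$P2[, , , ei], c(N, L, K))
    qual <- paths$P1 > thresholds$gamma & p2 > thresholds$tau
  } else {
    pq <- function() .path_gs(paths, "P_quali", thresholds$c1, "c1_grid") >
      thresholds$epsilon
    pt <- function() .path_gs(paths, "P_quanti", thresholds$c2, "c2_grid") >
      thresholds$epsilon
    inter <- switch(thresholds$gs_mode,
                    quali = pq(), quanti = pt(),
                    either = pq() | pt(), both = pq() & pt())
    qual <- (paths$P1 > thresholds$gamma) &
      array(rep(inter, K), c(N, L, K))
  }
  # vectorized first-firing-look search; only firing replications need the
  # per-subset extraction
  any_q <- matrix(rowSums(matrix(qual, N * L, K)) > 0, N, L)
  fired <- rowSums(any_q) > 0
  first <- max.col(any_q, ties.method = "first")
  classification <- rep("entire_population", N)
  look <- rep(NA_integer_, N)
  for (r in which(fired)) {
    a <- first[r]
    sel <- which(qual[r, a, ])
    if (thresholds$rule == "millen" && length(sel) == 2L) {
      sel <- which.max(paths$P1[r, a, ])
    }
    classification[r] <- classification_label(subsets[sel])
    look[r] <- a
  }
  list(classification = classification, enrichment_look = look)
}

.path_gs <- function(paths, field, cutoff, gridname) {
  if (is.null(cutoff)) stop("missing Gail-Simon cutoff", call. = FALSE)
  ci <- match(cutoff, paths[[gridname]])
  if (is.na(ci)) {
    stop(sprintf("cutoff %g not tabulated in these paths", cutoff),
         call. = FALSE)
  }
  paths[[field]][, , ci]
}

# Power of a set of classifications under a scenario truth: fraction of
# replications ending enriched entirely within the truly sensitive subsets.
.path_power <- function(classification, scenario) {
  sens <- scenario$sensitive
  if (!length(sens)) return(NA_real_)
  mean(vapply(strsplit(classification, "+", fixed = TRUE), function(s) {
    !identical(s, "entire_population") && all(s %in% sens)
  }, logical(1)))
}

#' Calibrate the decision thresholds by grid search
#'
#' For every candidate threshold combination, estimates the design-level
#' false positive rate under the null scenario and the mean enrichment
#' power over the effect scenarios (all grid points sharing the same
#' simulated trajectories — common random numbers), then returns the
#' combination with the highest power among those controlling the false
#' positive rate at `alpha_target`.  A fresh-seed validation run of the
#' returned thresholds on the null scenario is included.
#'
#' @param spec a [calibration_spec()].
#' @param rule `"millen"` (K = 2 only) or `"gail_simon"`.
#' @param gs_mode Gail-Simon combination mode (default `"either"`).
#' @param verbose print progress.
#' @return An object of class `calibration_result`: `thresholds` (an
#'   [enrich_thresholds()]), `grid` (the full grid report: one row per
#'   combination with estimated FPR and power), and `validation`
#'   (fresh-seed null FPR with its Monte-Carlo standard error).
#' @export
calibrate_thresholds <- function(spec, rule = c("millen", "gail_simon"),
                                 gs_mode = "either", verbose = FALSE) {
  stopifnot(inherits(spec, "calibration_spec"))
  rule <- match.arg(rule)
  g <- spec$grid
  sim <- function(sc) {
    simulate_decision_paths(sc, spec$n_total, spec$n_analyses, spec$prior,
                            spec$n_draws, spec$N_cal, spec$seed,
                            lam = spec$lam, eta_grid = g$eta,
                            c1_grid = g$c1, c2_grid = g$c2)
  }
  if (verbose) message("simulating null-scenario decision paths ...")
  null_paths <- sim(spec$null_scenario)
  if (verbose) message("simulating power-scenario decision paths ...")
  power_paths <- lapply(spec$power_scenarios, sim)
  combos <- if (rule == "millen") {
    expand.grid(gamma = g$gamma, eta = g$eta, tau = g$tau,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(gamma = g$gamma, epsilon = g$epsilon, c1 = g$c1, c2 = g$c2,
                KEEP.OUT.ATTRS = FALSE)
  }
  mk_thr <- function(row) {
    if (rule == "millen") {
      enrich_thresholds(gamma = row$gamma, lam = spec$lam, eta = row$eta,
                        tau = row$tau, rule = "millen")
    } else {
      enrich_thresholds(gamma = row$gamma, lam = spec$lam,
                        epsilon = row$epsilon, c1 = row$c1, c2 = row$c2,
                        rule = "gail_simon", gs_mode = gs_mode)
    }
  }
  fpr <- power <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    thr <- mk_thr(combos[i, , drop = FALSE])
    cls_null <- classify_paths(null_paths, thr)$classification
    fpr[i] <- mean(cls_null != "entire_population")
    power[i] <- mean(vapply(seq_along(power_paths), function(j) {
      .path_power(classify_paths(power_paths[[j]], thr)$classification,
                  spec$power_scenarios[[j]])
    }, numeric(1)))
  }
  grid_report <- cbind(combos, fpr = fpr, power = power)
  feasible <- which(fpr <= spec$alpha_target)
  if (!length(feasible)) {
    stop(sprintf(paste0("no grid point controls the false positive rate at ",
                        "%.3f; best achieved FPR = %.4f"),
                 spec$alpha_target, min(fpr)), call. = FALSE)
  }
  best <- feasible[order(-power[feasible], fpr[feasible])][1L]
  thresholds <- mk_thr(combos[best, , drop = FALSE])
  if (verbose) message("validating the selected thresholds on a fresh seed ...")
  val <- replicate_trials(spec$null_scenario, thresholds, spec$n_total,
                          spec$n_analyses, spec$prior, spec$n_draws,
                          N = spec$N_cal,
                          master_seed = derive_seed(spec$seed, 99L, 1L))
  p <- val$false_positive_rate
  structure(list(thresholds = thresholds, grid = grid_report,
                 selected = grid_report[best, , drop = FALSE],
                 validation = list(fpr = p, N = val$N,
                                   mc_se = sqrt(p * (1 - p) / val$N)),
                 alpha_target = spec$alpha_target, rule = rule),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibrated thresholds (%s rule, alpha target %.3f):\n",
              x$rule, x$alpha_target))
  print(x$thresholds)
  cat(sprintf("Grid-point estimates: FPR = %.4f, power = %.4f (of %d points)\n",
              x$selected$fpr, x$selected$power, nrow(x$grid)))
  cat(sprintf("Fresh-seed validation: FPR = %.4f (MC SE %.4f, N = %d)\n",
              x$validation$fpr, x$validation$mc_se, x$validation$N))
  invisible(x)
}
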