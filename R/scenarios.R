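# Data-generating scenarios: the simulated truth of one trial world.

#' Define a data-generating scenario
#'
#' A scenario fixes the biomarker partition (K subsets with prevalences
#' pi_k), the per-subset experimental-arm allocation probabilities q_k, and
#' the per-arm response (death) probabilities p_jk, from which the true
#' subset-level relative risks theta_k = p_1k / p_0k and the overall
#' relative risk follow.
#'
#' @param p1,p0 named numeric vectors of response probabilities in the
#'   experimental (arm 1) and control (arm 0) arms, one entry per subset;
#'   names are the subset labels (defaults to `LETTERS`).
#' @param pi prevalence vector, summing to 1.
#' @param q per-subset probability of allocation to the experimental arm
#'   (default 0.5 everywhere: randomization stratified on the subset).
#' @param label free-text scenario label.
#' @param null logical: is this a null configuration (no subset with a
#'   treatment-by-subset interaction), under which any enrichment is a false
#'   positive?  Defaults to `TRUE` when all theta_k are equal.
#' @return An object of class `enrich_scenario` with derived fields
#'   `theta` (true subset relative risks), `rr_overall` (overall relative
#'   risk under the prevalence mix), and `sensitive` (labels with
#'   `theta_k < 1`, the truly beneficial subsets).
#' @examples
#' scenario(p1 = c(A = 0.2, B = 0.4), p0 = c(A = 0.5, B = 0.4))
#' @export
scenario <- function(p1, p0, pi = NULL, q = NULL, label = "", null = NULL) {
  K <- length(p1)
  if (K < 2L) stop("a scenario needs K >= 2 subsets", call. = FALSE)
  if (length(p0) != K) stop("'p1' and 'p0' must have equal length", call. = FALSE)
  subsets <- names(p1)
  if (is.null(subsets)) subsets <- LETTERS[seq_len(K)]
  if (is.null(pi)) pi <- rep(1 / K, K)
  if (is.null(q)) q <- rep(0.5, K)
  if (length(pi) != K || length(q) != K) {
    stop("'pi' and 'q' must have one entry per subset", call. = FALSE)
  }
  .assert_prob(p1, "p1"); .assert_prob(p0, "p0")
  .assert_prob(pi, "pi"); .assert_prob(q, "q")
  if (abs(sum(pi) - 1) > 1e-8) stop("'pi' must sum to 1", call. = FALSE)
  if (any(p0 == 0 & p1 > 0)) {
    stop("theta_k must be finite: p0 = 0 requires p1 = 0", call. = FALSE)
  }
  names(p1) <- names(p0) <- names(pi) <- names(q) <- subsets
  theta <- ifelse(p0 > 0, p1 / p0, 1)
  rr <- sum(pi * p1) / sum(pi * p0)
  if (is.null(null)) null <- length(unique(round(theta, 10))) == 1L
  structure(list(K = K, subsets = subsets, p1 = p1, p0 = p0, pi = pi, q = q,
                 theta = stats::setNames(theta, subsets), rr_overall = rr,
                 sensitive = subsets[theta < 1], null = null, label = label),
            class = "enrich_scenario")
}

#' @export
print.enrich_scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: K = %d subsets (%s)%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$K, paste(x$subsets, collapse = ", "),
              if (x$null) " [null]" else ""))
  print(round(data.frame(pi = x$pi, q = x$q, p1 = x$p1, p0 = x$p0,
                         theta = x$theta), 3))
  cat(sprintf("Overall relative risk: %.3f\n", x$rr_overall))
  invisible(x)
}

#' Built-in two-subset simulation scenarios
#'
#' The four K = 2 benchmark configurations used by the simulation study
#' (n = 800, pi = 0.5, balanced allocation): scenario 1 is the null (no
#' benefit anywhere, worse prognosis in subset B); scenarios 2-4 plant an
#' increasing benefit in subset A (theta_A = 0.75, 0.54, 0.40) with no
#' effect in subset B.
#'
#' @param pi_A prevalence of subset A (default 0.5).
#' @param q_A,q_B experimental-arm allocation probabilities (default 0.5).
#' @return Named list of four [scenario()] objects.
#' @export
k2_scenarios <- function(pi_A = 0.5, q_A = 0.5, q_B = 0.5) {
  pi <- c(A = pi_A, B = 1 - pi_A)
  q <- c(A = q_A, B = q_B)
  mk <- function(p1A, p0A, lab, null = NULL)
    scenario(p1 = c(A = p1A, B = 0.40), p0 = c(A = p0A, B = 0.40),
             pi = pi, q = q, label = lab, null = null)
  list(scenario1 = scenario(p1 = c(A = 0.30, B = 0.40),
                            p0 = c(A = 0.30, B = 0.40), pi = pi, q = q,
                            label = "K2 scenario 1 (null)", null = TRUE),
       scenario2 = mk(0.30, 0.40, "K2 scenario 2 (mild benefit in A)"),
       scenario3 = mk(0.20, 0.37, "K2 scenario 3 (marked benefit in A)"),
       scenario4 = mk(0.20, 0.50, "K2 scenario 4 (large interaction)"))
}

#' Built-in three-subset simulation scenarios
#'
#' The seven K = 3 benchmark configurations (equal prevalence by default):
#' scenario 1 null; scenario 2 uniform benefit (theta = 0.8 everywhere);
#' scenarios 3-5 quantitative interactions with benefit concentrated in C
#' (and B); scenarios 6-7 qualitative interactions (benefit in B, harm in
#' C, no effect in A).
#'
#' @param pi length-3 prevalence vector (default `rep(1/3, 3)`); see
#'   [k3_prevalence_patterns()].
#' @param q length-3 experimental-arm allocation vector (default 0.5).
#' @return Named list of seven [scenario()] objects.
#' @export
k3_scenarios <- function(pi = rep(1 / 3, 3), q = rep(0.5, 3)) {
  names(pi) <- names(q) <- c("A", "B", "C")
  mk <- function(p1, p0, lab, null = NULL)
    scenario(p1 = stats::setNames(p1, c("A", "B", "C")),
             p0 = stats::setNames(p0, c("A", "B", "C")),
             pi = pi, q = q, label = lab, null = null)
  list(scenario1 = mk(c(.40, .40, .40), c(.40, .40, .40),
                      "K3 scenario 1 (null)", null = TRUE),
       scenario2 = mk(c(.32, .32, .32), c(.40, .40, .40),
                      "K3 scenario 2 (uniform benefit)"),
       scenario3 = mk(c(.40, .40, .20), c(.40, .40, .50),
                      "K3 scenario 3 (high efficacy in C)"),
       scenario4 = mk(c(.40, .24, .24), c(.40, .40, .40),
                      "K3 scenario 4 (moderate efficacy in B and C)"),
       scenario5 = mk(c(.40, .24, .20), c(.40, .40, .50),
                      "K3 scenario 5 (moderate B, high C)"),
       scenario6 = mk(c(.40, .24, .50), c(.40, .40, .40),
                      "K3 scenario 6 (qualitative: benefit B, harm C)"),
       scenario7 = mk(c(.40, .20, .50), c(.40, .50, .40),
                      "K3 scenario 7 (qualitative: strong benefit B, harm C)"))
}

#' Prevalence patterns for the K = 3 sensitivity analyses
#'
#' The five prevalence patterns of the three-subset sensitivity study:
#' pattern 1 balanced, patterns 2-5 progressively shifting mass between
#' subsets A and C.
#'
#' @return A list of five length-3 prevalence vectors.
#' @export
k3_prevalence_patterns <- function() {
  lab <- c("A", "B", "C")
  list(pattern1 = stats::setNames(c(1 / 3, 1 / 3, 1 / 3), lab),
       pattern2 = stats::setNames(c(1 / 6, 1 / 3, 2 / 4), lab),
       pattern3 = stats::setNames(c(11 / 18, 1 / 3, 1 / 18), lab),
       pattern4 = stats::setNames(c(1 / 3, 2 / 4, 1 / 6), lab),
       pattern5 = stats::setNames(c(1 / 3, 1 / 18, 11 / 18), lab))
}

#' Balance-preserving allocation for K = 2 imbalance sweeps
#'
#' Given an experimental-arm allocation probability `q_A` in subset A, the
#' allocation in subset B that keeps the overall trial 1:1 is
#' `q_B = (0.5 - pi_A * q_A) / (1 - pi_A)`.
#'
#' @param q_A allocation probability in subset A.
#' @param pi_A prevalence of subset A.
#' @return `q_B`; errors if the implied value falls outside `(0, 1)`.
#' @export
balanced_q_B <- function(q_A, pi_A = 0.5) {
  q_B <- (0.5 - pi_A * q_A) / (1 - pi_A)
  if (q_B <= 0 || q_B >= 1) {
    stop(sprintf("q_A = %g with pi_A = %g implies q_B = %g outside (0,1)",
                 q_A, pi_A, q_B), call. = FALSE)
  }
  q_B
}
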