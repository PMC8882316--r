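---
title: "Bayesian adaptive enrichment designs with benrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian adaptive enrichment designs with benrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benrich)
```

## The design problem

A two-arm randomized trial enrolls a heterogeneous population partitioned
into $K \ge 2$ subsets by a categorical classifier biomarker $X$ (e.g. an
organ-dysfunction score measured at baseline), with prevalence $\pi_k$ per
subset. The outcome $Y \in \{0, 1\}$ is binary and unfavorable when 1
(death), and patients are allocated to the experimental arm with
probability $q_k$ within subset $k$. If the treatment only helps in some
subsets, an all-comers trial can be negative overall while a *sensitive*
subpopulation benefits. An adaptive enrichment design addresses this
during accrual: at scheduled interim analyses it looks for
treatment-by-subset interaction together with subset-level efficacy, and
when both are found it stops enrolling the non-benefiting subsets,
redirecting the remaining accrual to the sensitive one(s).

Within arm $j \in \{0, 1\}$ and subset $k$, the death probability is
$p_{jk}$ and the subset-level treatment effect is the relative risk
$\theta_k = p_{1k} / p_{0k}$, with $\theta_k < 1$ favoring the
experimental arm; $\theta$ denotes the overall relative risk.

## Posterior model

Each $p_{jk}$ gets an independent $\mathrm{Beta}(\alpha, \beta)$ prior
(non-informative $\mathrm{Beta}(1,1)$ by default), so with $y_{jk}$ events
among $n_{jk}$ patients the posterior is
$\mathrm{Beta}(\alpha + y_{jk},\, \beta + n_{jk} - y_{jk})$ — the model is
fully conjugate. `sample_posterior()` therefore draws exact independent
Monte-Carlo samples of every $p_{jk}$, forms matched draws of
$\theta_k = p_{1k}/p_{0k}$, and never needs MCMC: the sampled posterior is
exact, with zero autocorrelation, at any number of draws.

Two quantities feed the decision rules:

* **Influence (efficacy) condition**, per subset:
  $P_{1k} = P(\theta_k < \lambda \mid \text{Data})$, with $\lambda$ the
  minimal clinically relevant effect size ($\lambda = 0.9$ by default, a
  fixed design input that is *not* calibrated). The rule fires when
  $P_{1k} > \gamma$.
* **Interaction condition**, via one of two criteria:
  * *Millen's conditional ratio* ($K = 2$ only):
    $P_{2k} = P(\theta_t/\theta_k > \eta \mid \theta_t \ge \theta_k,
    \text{Data})$ where $t$ is the complementary subset and $\eta \ge 1$
    the minimal interaction ratio; fires when $P_{2k} > \tau$.
  * *Bayesianized Gail–Simon statistics* (any $K \ge 2$): per posterior
    draw $i$, with $\beta_{ki} = \log \theta_{ki}$ standardized by
    $\sigma_k$,
    $Q^-_i = \sum_k \mathbf{1}(\beta_{ki} < 0)(\beta_{ki}/\sigma_k)^2$ and
    $Q^+_i$ its positive-sign counterpart. Qualitative interaction
    (opposite directions):
    $P_{quali} = P(\min\{Q^-, Q^+\} > C_1 \mid \text{Data})$; quantitative
    interaction (same direction, different size):
    $P_{quanti} = P(\sum_k (\theta_k - \theta) > C_2 \mid \text{Data})$.
    The rule fires when $P_{quali} > \varepsilon$ and/or
    $P_{quanti} > \varepsilon$ (mode `"either"` by default, as the rule is
    printed "or/and"; `"quali"`, `"quanti"` and `"both"` are exposed).

A subset is enriched at an analysis iff its influence condition *and* the
interaction condition both hold (strict inequalities throughout); with
$K > 2$ several subsets can qualify simultaneously. Otherwise the trial
continues in the entire population. After the first enrichment the rules
are frozen: later analyses only update estimates. All subset-level and
global estimates are posterior means with equal-tailed 95% credibility
intervals (2.5/97.5% quantiles).

## Design choices where the construction was open

Several details of the statistics admit more than one reading; the package
fixes them as follows.

* **$\sigma_k$ in the Gail–Simon statistic.** The statistic mixes per-draw
  $\beta_k$ values with "its standard error". We take $\sigma_k$ to be the
  posterior standard deviation of $\log\theta_k$, estimated once from the
  full draw matrix and held fixed across draws, so that $Q^\pm$ have a
  genuine posterior distribution induced by the $\beta_k$ draws alone — the
  minimal reading that makes $P_{quali}$ a posterior probability. A
  frequentist delta-method plug-in from the counts is available
  (`gail_simon_draws(..., sigma_method = "plugin")`).
* **The global $\theta$ in $P_{quanti}$.** The posterior of the overall
  effect is built by pooling events and totals across subsets within each
  arm and applying the same conjugate update, with draws matched by index
  to the subset-level draws (variance reduction). A prevalence-weighted
  alternative that averages the matched $p_{jk}$ draws is available
  (`global_method = "weighted"`).
* **Per-draw versus posterior-mean reading of $P_{quanti}$.** We evaluate
  $\sum_k(\theta_k - \theta)$ per draw, making $P_{quanti}$ a true
  posterior probability; plugging in posterior means would make it
  degenerate (0 or 1).
* **Millen orientation and ties.** Evaluating enrichment of subset $k$,
  $t$ is the other subset and the ratio is oriented so that large values
  favor enriching $k$. If both subsets somehow qualify (possible only near
  $\eta = 1$), the tie breaks deterministically toward the larger
  $P_{1k}$, and the event is logged.
* **Empty conditioning event.** If no draw satisfies
  $\theta_t \ge \theta_k$, $P_{2k}$ is reported as 0 with conditioning
  fraction 0 (a warning in `millen_probability()`; the decision engine
  reads it as absence of interaction evidence) rather than NaN.
* **Enrichment permanence.** The first enrichment freezes interaction
  evaluation for the rest of the trial, matching the sequential workflow
  of the real-data analysis mode; `re_evaluate_after_enrichment = TRUE`
  allows further narrowing among survivors when more than one subset was
  kept ($K > 2$).
* **Single active subset.** With one active subset no interaction is
  evaluable; analyses report estimates only.
* **Post-enrichment estimation.** Patients already enrolled in dropped
  subsets stay in the estimation set (their posteriors simply stop
  moving); they are excluded from further accrual only.

## The trial simulator

`run_trial()` enrolls `n_total` patients (default 800) in `n_analyses`
equal blocks (default 4: three interim analyses plus a terminal analysis,
every 200 patients — analyses are scheduled at fixed enrolled counts, not
calendar time). Enrollment is uniform: each patient's subset is drawn from
the prevalences renormalized over the currently active subsets, the arm is
Bernoulli($q_k$) and the outcome Bernoulli($p_{jk}$). Renormalizing the
prevalence after enrichment means dropped-subset slots are refilled by the
active subsets, so every replication enrolls exactly `n_total` patients.
`replicate_trials()` aggregates `N` independent replications into decision
proportions (over the exhaustive classification set), mean per-subset
sample sizes, estimation bias, false positive rate and power.

The built-in scenario catalogs `k2_scenarios()` and `k3_scenarios()`
encode the benchmark two- and three-subset configurations (null scenarios;
mild to large benefit confined to one subset; uniform benefit;
quantitative and qualitative interactions), `k3_prevalence_patterns()` the
five three-subset prevalence patterns, and `balanced_q_B()` the
allocation-imbalance sweeps in which $q_B$ is derived to keep the trial
1:1 overall.

The **false positive rate** under a null scenario is the proportion of
replications enriching any subset; under an effect scenario it is the
proportion whose enrichment includes a subset with no true benefit (the
two definitions coincide with how the benchmark tables report the
quantity). **Power** is the proportion of replications ending enriched
entirely within the truly sensitive subsets ($\theta_k < 1$):
mis-enrichment counts against power, not toward it.

What the simulator deliberately does *not* emulate: non-uniform or
time-varying accrual, calendar-time analysis scheduling, patient dropout,
overlapping or nested subsets, and non-binary endpoints. Passing tests
therefore speak to the design's behavior under clean uniform accrual with
a perfectly measured categorical biomarker, not to robustness against
those violations.

## Seed policy

Every source of randomness descends from one master seed through
deterministic integer mixing (`derive_seed()`): replication $r$ gets seed
$f(\text{master}, r)$, and within a replication each analysis draws its
accrual block and its posterior sample from seeds
$f(\text{rep seed}, \text{stream}, a)$. Replications are therefore
independent but bitwise reproducible, identical under serial and parallel
execution, and the real-trial replay (`analyze_trial()`) reproduces the
simulator's decision path exactly when given the same seed and patient
stream.

## Threshold calibration

The decision cutoffs ($\gamma$, $\eta$, $\tau$, $\varepsilon$, $C_1$,
$C_2$) have no defensible a-priori values, so none is hard-coded:
`calibrate_thresholds()` grid-searches them to control the design-level
false positive rate under a null scenario at `alpha_target` (default
0.05) while maximizing mean enrichment power over the effect scenarios
(the benchmark study uses the mild- and large-benefit scenarios for this
role). If no grid point satisfies the constraint, calibration fails
loudly, reporting the best achieved rate.

The search exploits a structural property: because the first enrichment
freezes rule evaluation, a replication's terminal classification is fully
determined by its pre-enrichment probability trajectory. Those
trajectories are simulated once per replication
(`simulate_decision_paths()`), with the interaction probabilities
tabulated at every candidate $\eta$, $C_1$, $C_2$; each grid point is then
evaluated by pure thresholding (`classify_paths()`). All grid points thus
share common random numbers, making comparisons low-variance and the
argmax stable, and the classifications agree *exactly* with running the
full simulator at that grid point (a unit test asserts this for both
rules). A fresh-seed validation run of the selected thresholds is always
reported alongside, since the selected grid point's in-sample rate is
biased by selection.

Default grids place the probability cutoffs $\gamma, \tau$ on
$\{0.80, 0.85, 0.90, 0.95\}$ around the 0.90 operating point used in the
worked real-trial analysis, and $\eta$ on $\{1.0, 1.1, 1.25, 1.5\}$. For
the Gail–Simon cutoffs the grids are deliberately wider:
$\varepsilon \in \{0.05, 0.10, 0.25, 0.50, 0.80, 0.85, 0.90, 0.95\}$,
$C_1 \in \{0.5, 1, 2, 3, 4, 6\}$ and
$C_2 \in \{0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1\}$. Two observations force
the wider ranges: restricting $C_1, C_2$ to small values leaves *no*
feasible grid point at $\alpha = 0.05$ for $K = 2$ (the quantitative
statistic fires too easily under the null), and the worked real-trial
tables show the Gail–Simon rule declaring enrichment at an interaction
probability of 0.08 — evidence that the relevant operating range for
$\varepsilon$ extends well below the 0.90 anchor, with the influence
cutoff $\gamma$ carrying most of the false-positive control. $\lambda$ is
a fixed design input and is never calibrated.

## Numerical choices and degenerate inputs

* Ties in the strict inequalities have probability zero under continuous
  draws; $\beta_k = 0$ exactly contributes to neither $Q^-$ nor $Q^+$.
* Degenerate zero-variance draws make $\sigma_k$ undefined and raise an
  error rather than propagating NaN.
* Zero events in an arm are handled exactly by the Beta posterior
  (support strictly inside $(0,1)$, so all relative-risk draws are finite
  and positive).
* A subset with no enrolled patients keeps its prior; under the
  non-informative prior its influence probability hovers near 0.45, so it
  cannot trigger enrichment at any sensible $\gamma$.
* Monte-Carlo sizes: analyses default to `n_draws = 10000` exact draws.
  The packaged acceptance workflow uses 4000 draws per analysis for
  replication runs and 2000 during calibration, with $N = 1000$
  replications per operating characteristic and $N_{cal} = 1000$ per grid
  point — sizes at which the Monte-Carlo standard error of a reported
  proportion is below 1.6 percentage points. The test suite uses smaller
  problem sizes for the structural checks, chosen so each property is
  still sharply separated from its failure mode.

## Worked example

A large quantitative interaction (strong benefit in subset A, none in B),
analysed with calibrated-scale Millen thresholds:

```{r example, eval = FALSE}
sc <- k2_scenarios()$scenario4
thr <- enrich_thresholds(gamma = 0.95, eta = 1.25, tau = 0.90,
                         rule = "millen")
oc <- replicate_trials(sc, thr, n_total = 800, n_analyses = 4,
                       n_draws = 4000, N = 500, master_seed = 1)
oc
tabulate_decisions(oc)
trajectory_table(oc)
```

Nearly every replication enriches subset A, typically at the first or
second interim analysis, and the mean terminal sample size in A rises to
roughly 650 of the 800 patients as accrual is redirected. The real-trial
mode replays the same rules on a patient-level CSV:

```{r analyze, eval = FALSE}
ds <- read_trial_csv("trial.csv", date = "enroll_date",
                     partitions = c("sofa_neuro", "age_group"))
analyze_trial(ds, partition = "sofa_neuro",
              calendar = c(194, 388, 582, 776), thresholds = thr,
              n_draws = 10000, seed = 1)
```

## Known limitations

* The Millen criterion is defined for exactly two subsets; for $K > 2$
  only the Gail–Simon rule is available.
* The calibrated thresholds are specific to the null/power scenarios,
  schedule and sample size used in the calibration spec; a different
  design must be recalibrated.
* The design never stops early for overall futility or efficacy — the
  trial always runs to `n_total` enrolled.
* Enrichment decisions based on few events (first interim with rare
  outcomes) inherit the full noise of the posterior; the benchmark
  schedule (first look at 200 patients) should be treated as a floor, not
  a recommendation.
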