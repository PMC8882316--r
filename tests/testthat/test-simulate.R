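test_that("patient generation honors prevalence, allocation and outcome truths", {
  sc <- scen4()
  pat <- generate_patients(sc, 4000, seed = 1)
  expect_lt(abs(mean(pat$subset == "A") - 0.5), 3 * sqrt(0.25 / 4000))
  # restriction to a singleton routes every patient there
  patA <- generate_patients(sc, 200, active_subsets = "A", seed = 2)
  expect_true(all(patA$subset == "A"))
  # experimental arm of subset A dies at rate p_1A = 0.20
  sel <- pat$subset == "A" & pat$arm == 1
  expect_gt(sum(sel), 500)
  expect_lt(abs(mean(pat$outcome[sel]) - 0.20),
            3 * sqrt(0.2 * 0.8 / sum(sel)))
  expect_error(generate_patients(sc, 10, active_subsets = "Z"), "subset")
})

test_that("every trial enrolls exactly n_total patients", {
  for (seed in 1:4) {
    r <- run_trial(scen4(), thr_easy(), n_total = 400, n_analyses = 4,
                   n_draws = 800, master_seed = seed)
    expect_equal(sum(r$n_k), 400)
    expect_true(all(r$cum_n[4, ] == r$n_k))
  }
  expect_error(run_trial(scen4(), thr_easy(), n_total = 801, n_analyses = 4),
               "equal analysis blocks")
})

test_that("run_trial is reproducible from its master seed", {
  a <- run_trial(scen2(), thr_easy(), n_total = 400, n_draws = 1000,
                 master_seed = 31, keep_patients = TRUE)
  b <- run_trial(scen2(), thr_easy(), n_total = 400, n_draws = 1000,
                 master_seed = 31, keep_patients = TRUE)
  expect_identical(a$final_action, b$final_action)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$patients, b$patients)
})

test_that("unreachable thresholds keep the entire population and recover theta", {
  oc <- replicate_trials(scen2(), thr_unreachable(), n_total = 800,
                         n_draws = 1500, N = 40, master_seed = 17)
  expect_identical(unname(oc$decision_proportions["entire_population"]), 1)
  expect_equal(sum(oc$decision_proportions), 1)
  expect_identical(unname(oc$false_positive_rate), 0)
  # parameter recovery: posterior mean of theta_k close to the truth
  expect_lt(max(abs(oc$mean_bias_theta_k)), 0.1)
})

test_that("replicate aggregates are sound and parallel equals serial", {
  oc1 <- replicate_trials(scen4(), thr_easy(), n_total = 400, n_draws = 800,
                          N = 1, master_seed = 5)
  expect_identical(sum(oc1$decision_proportions == 1), 1L)  # point mass
  oc <- replicate_trials(scen4(), thr_easy(), n_total = 400, n_draws = 800,
                         N = 12, master_seed = 5)
  expect_equal(sum(oc$decision_proportions), 1)
  expect_equal(sum(oc$mean_n_k), 400)
  ocp <- replicate_trials(scen4(), thr_easy(), n_total = 400, n_draws = 800,
                          N = 12, master_seed = 5, cores = 2)
  expect_identical(oc$decision_proportions, ocp$decision_proportions)
  expect_identical(oc$mean_n_k, ocp$mean_n_k)
  expect_identical(oc$mean_bias_theta_k, ocp$mean_bias_theta_k)
})

test_that("enrichment redirects accrual toward the enriched subset", {
  # forced early enrichment in A: mean n_A far above n * pi_A
  oc <- replicate_trials(scen4(), thr_easy(), n_total = 400, n_draws = 800,
                         N = 20, master_seed = 9)
  expect_gt(oc$mean_n_k["A"], 400 * 0.5 * 1.2)
  expect_gt(unname(oc$decision_proportions["A"]), 0.9)
})

test_that("decision-path classification reproduces the simulator exactly", {
  # Millen, K = 2
  thr_m <- enrich_thresholds(gamma = 0.9, eta = 1.25, tau = 0.9,
                             rule = "millen")
  oc <- replicate_trials(scen2(), thr_m, n_draws = 1000, N = 25,
                         master_seed = 77, keep_results = TRUE)
  paths <- simulate_decision_paths(scen2(), n_draws = 1000, N = 25,
                                   master_seed = 77,
                                   eta_grid = c(1, 1.25),
                                   c1_grid = 1, c2_grid = 0.1)
  cls <- classify_paths(paths, thr_m)
  expect_identical(cls$classification,
                   unname(vapply(oc$results, `[[`, character(1),
                                 "final_action")))
  expect_identical(cls$enrichment_look,
                   unname(vapply(oc$results, `[[`, integer(1),
                                 "enrichment_look")))
  # Gail-Simon, K = 3
  thr_g <- enrich_thresholds(gamma = 0.9, epsilon = 0.25, c1 = 1, c2 = 0.1,
                             rule = "gail_simon")
  sc3 <- k3_scenarios()$scenario5
  oc3 <- replicate_trials(sc3, thr_g, n_draws = 1000, N = 25,
                          master_seed = 78, keep_results = TRUE)
  paths3 <- simulate_decision_paths(sc3, n_draws = 1000, N = 25,
                                    master_seed = 78, eta_grid = 1,
                                    c1_grid = 1, c2_grid = 0.1)
  cls3 <- classify_paths(paths3, thr_g)
  expect_identical(cls3$classification,
                   unname(vapply(oc3$results, `[[`, character(1),
                                 "final_action")))
})

test_that("derived seeds are deterministic and within integer range", {
  expect_identical(derive_seed(123, 1, 5), derive_seed(123, 1, 5))
  expect_false(derive_seed(123, 1, 5) == derive_seed(123, 1, 6))
  expect_false(derive_seed(123, 1, 5) == derive_seed(124, 1, 5))
  s <- vapply(1:200, function(i) derive_seed(42, 3, i), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(anyDuplicated(s), 0L)
})
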