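test_that("unreachable thresholds always continue with the entire population", {
  for (rule in c("millen", "gail_simon")) {
    dec <- evaluate_analysis(counts_strong_A(), c("A", "B"),
                             thr_unreachable(rule), n_draws = 2000, seed = 1)
    expect_identical(dec$action, "continue_entire_population")
    expect_length(dec$enriched_subsets, 0)
  }
})

test_that("a strong planted benefit in A triggers enrichment in A", {
  dec <- evaluate_analysis(counts_strong_A(), c("A", "B"), thr_easy(),
                           n_draws = 4000, seed = 2)
  expect_identical(dec$action, "enrich")
  expect_identical(dec$enriched_subsets, "A")
  ev <- dec$evidence
  expect_true(ev$influence_met[ev$subset == "A"])
  expect_true(ev$interaction_met[ev$subset == "A"])
  expect_false(ev$qualifies[ev$subset == "B"])
})

test_that("K = 3 Gail-Simon enrichment can select two subsets simultaneously", {
  cts <- subset_arm_counts(
    events = matrix(c(40, 40, 50, 10, 50, 10), 2,
                    dimnames = list(NULL, c("A", "B", "C"))),
    totals = matrix(100, 2, 3))
  thr <- enrich_thresholds(gamma = 0.5, epsilon = 0.5, c1 = 0.5, c2 = 0,
                           rule = "gail_simon")
  dec <- evaluate_analysis(cts, c("A", "B", "C"), thr, n_draws = 4000,
                           seed = 3)
  expect_identical(dec$action, "enrich")
  expect_setequal(dec$enriched_subsets, c("B", "C"))
})

test_that("Millen's rule errors for K > 2 active subsets", {
  cts <- subset_arm_counts(events = matrix(10, 2, 3),
                           totals = matrix(50, 2, 3))
  expect_error(evaluate_analysis(cts, colnames(cts$events), thr_easy(),
                                 n_draws = 500, seed = 1), "K = 2")
})

test_that("the enrichment state machine freezes after enrichment", {
  dec <- evaluate_analysis(counts_strong_A(), c("A", "B"), thr_easy(),
                           n_draws = 2000, seed = 2)
  st <- update_enrichment_state(c("A", "B"), dec)
  expect_identical(st$active, "A")
  expect_true(st$frozen)
  # continue decision leaves any state untouched
  dec_c <- evaluate_analysis(counts_strong_A(), c("A", "B"),
                             thr_unreachable(), n_draws = 2000, seed = 2)
  st2 <- update_enrichment_state(c("A", "B", "C"), dec_c)
  expect_identical(st2$active, c("A", "B", "C"))
  expect_false(st2$frozen)
  # multi-subset enrichment freezes the same way
  cts <- subset_arm_counts(
    events = matrix(c(40, 40, 50, 10, 50, 10), 2,
                    dimnames = list(NULL, c("A", "B", "C"))),
    totals = matrix(100, 2, 3))
  thr <- enrich_thresholds(gamma = 0.5, epsilon = 0.5, c1 = 0.5, c2 = 0,
                           rule = "gail_simon")
  dec3 <- evaluate_analysis(cts, c("A", "B", "C"), thr, n_draws = 4000,
                            seed = 3)
  st3 <- update_enrichment_state(c("A", "B", "C"), dec3)
  expect_setequal(st3$active, c("B", "C"))
  expect_true(st3$frozen)
})

test_that("decisions are deterministic and monotone in the cutoffs", {
  cts <- counts_strong_A()
  d1 <- evaluate_analysis(cts, c("A", "B"), thr_easy(), n_draws = 2000,
                          seed = 11)
  d2 <- evaluate_analysis(cts, c("A", "B"), thr_easy(), n_draws = 2000,
                          seed = 11)
  expect_identical(d1$evidence, d2$evidence)
  expect_identical(d1$action, d2$action)
  # raising gamma / tau never converts continue into enrich (same seed)
  set.seed(99)
  for (rep in 1:6) {
    y <- matrix(rbinom(4, 60, 0.35), 2, dimnames = list(NULL, c("A", "B")))
    cts_r <- subset_arm_counts(y, matrix(60, 2, 2))
    fired <- vapply(c(0.5, 0.7, 0.9, 1), function(g) {
      thr <- enrich_thresholds(gamma = g, eta = 1.1, tau = g, rule = "millen")
      evaluate_analysis(cts_r, c("A", "B"), thr, n_draws = 1000,
                        seed = 7)$action == "enrich"
    }, logical(1))
    expect_true(all(diff(fired) <= 0))  # once off, stays off as cutoffs rise
  }
})

test_that("an empty subset never satisfies the influence condition at gamma >= 0.5", {
  cts <- subset_arm_counts(events = matrix(c(20, 20, 0, 0), 2,
                                           dimnames = list(NULL, c("A", "B"))),
                           totals = matrix(c(60, 60, 0, 0), 2))
  thr <- enrich_thresholds(gamma = 0.5, eta = 1, tau = 0.01, rule = "millen")
  dec <- evaluate_analysis(cts, c("A", "B"), thr, n_draws = 4000, seed = 4)
  ev <- dec$evidence
  expect_false(ev$influence_met[ev$subset == "B"])
})
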