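test_that("trial-count benchmark matches the analytic expectation at small n", {
  res <- run_trials_experiment(n_values = c(10, 15), p_values = 0.8,
                               replicates = 600, seed = 2)
  expect_identical(res$n, c(10, 15))
  for (i in seq_len(nrow(res))) {
    expect_lt(abs(res$mean_trials[i] - res$expected[i]), 3 * res$se_trials[i])
    expect_lte(res$mean_trials[i], res$theory_envelope[i])
  }
})

test_that("a certain prior needs exactly one trial per replicate", {
  res <- run_trials_experiment(n_values = 12, p_values = 1, replicates = 50,
                               seed = 3)
  expect_equal(res$mean_trials, 1)
  expect_equal(res$se_trials, 0)
})

test_that("the trial-count benchmark is reproducible from its master seed", {
  a <- run_trials_experiment(10, 0.8, replicates = 100, seed = 11)
  b <- run_trials_experiment(10, 0.8, replicates = 100, seed = 11)
  expect_identical(a, b)
})

test_that("trajectory lengths are short, bounded, and grow with network size", {
  res <- run_trajectory_length_experiment(n_values = c(5, 10, 20, 50),
                                          replicates = 60, seed = 4)
  expect_true(all(res$mean_transient[res$n == 5] <= 2^5))
  # qualitative growth: transients at the largest size exceed the smallest
  expect_gt(res$mean_transient[res$n == 50], res$mean_transient[res$n == 5])
  rho <- cor(res$n, res$mean_transient, method = "spearman")
  expect_gt(rho, 0)
})

test_that("guided search needs no more total steps than random restarts", {
  res <- run_comparison_experiment(n_values = c(10, 20), p = 0.9,
                                   replicates = 40, seed = 6)
  for (i in seq_len(nrow(res))) {
    margin <- 3 * sqrt(res$se_apriori[i]^2 + res$se_random[i]^2)
    expect_lte(res$mean_total_steps_apriori[i],
               res$mean_total_steps_random[i] + margin)
  }
  # both methods verifiably reached the same canonical target: totals finite
  expect_true(all(is.finite(res$mean_total_steps_apriori)))
  expect_true(all(is.finite(res$mean_total_steps_random)))
})

test_that("a certain prior inside the target attractor needs one trajectory", {
  # guess = a state of the target attractor, p = 1: the only trial starts
  # inside the cycle, so zero transient steps accumulate
  net <- generate_nk(10, 2, seed = 8)
  target <- extract_attractor(simulate_to_attractor(net, random_state(10, seed = 9)))
  it_prior <- uniform_prior(target$cycle[[1]], 1)
  res <- attapriori(net, it_prior, mode = "collect_all")
  expect_equal(res$trials_used, 1)
  expect_equal(res$total_transient_steps, 0)
  expect_identical(attractor_keys(res$attractors),
                   attractor_keys(list(target)))
})

test_that("scenario sweeps hold fixed nodes and cover the confidence grid", {
  net <- parse_network("targets, factors
in1, in1
a, in1 & !b
b, a | c
c, !in1")
  sweep <- run_scenario_sweep(net, fixed = c(in1 = 1L), scenarios = "off",
                              confidences = c(0.7, 1), seed = 5)
  expect_identical(sort(unique(sweep$confidence)), c(0.7, 1))
  # confidence 1: a single trial (the guess) per scenario
  expect_true(all(sweep$trials_used[sweep$confidence == 1] == 1))
  # confidence 0.7 with 3 free bits: exhausts 2^3 start vectors
  expect_true(all(sweep$trials_used[sweep$confidence == 0.7] == 8))
})

test_that("an unfixed sweep on the example reproduces the full census", {
  net <- example_net()
  sweep <- run_scenario_sweep(net, scenarios = "off", confidences = 0.7,
                              seed = 5)
  expect_identical(sort(unique(sweep$states)),
                   attractor_keys(enumerate_all_attractors(net)))
  expect_error(run_scenario_sweep(net, fixed = c(nope = 1L)), "not in the network")
})
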