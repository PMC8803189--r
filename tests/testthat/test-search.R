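test_that("a guess that is itself a fixed point is found at trial 1", {
  net <- example_net()
  res <- attapriori(net, uniform_prior(c(0L, 0L, 0L), 0.9))
  expect_equal(res$trials_used, 1)
  expect_identical(res$termination_reason, "criteria_met")
  expect_identical(res$attractors[[res$hits[1]]]$cycle[[1]], c(0L, 0L, 0L))
})

test_that("period criteria reject trial 1 and accept the period-2 cycle at trial 2", {
  net <- example_net()
  res <- attapriori(net, uniform_prior(c(1L, 1L, 0L), 0.9),
                    attractor_criteria(period_min = 2))
  expect_equal(res$trials_used, 2)
  hit <- res$attractors[[res$hits[1]]]
  expect_identical(hit$period, 2L)
  expect_identical(attractor_keys(list(hit)), "011|100")
})

test_that("collect-all reproduces the exhaustive census of the example", {
  net <- example_net()
  res <- attapriori(net, uniform_prior(c(0L, 0L, 0L), 0.9), mode = "collect_all")
  expect_equal(res$trials_used, 8)
  expect_identical(res$termination_reason, "exhausted")
  expect_identical(attractor_keys(res$attractors),
                   attractor_keys(enumerate_all_attractors(net)))
})

test_that("collect-all equals brute-force enumeration on random networks", {
  for (s in 1:25) {
    net <- generate_nk(8, 2, seed = 2000 + s)
    res <- attapriori(net, uniform_prior(random_state(8, seed = s), 0.8),
                      mode = "collect_all")
    expect_equal(res$trials_used, 256)
    expect_identical(attractor_keys(res$attractors),
                     attractor_keys(enumerate_all_attractors(net)),
                     label = paste("seed", 2000 + s))
  }
})

test_that("required node values are enforced stably across the cycle", {
  net <- example_net()
  # the period-2 cycle oscillates x1; requiring x1 = 1 stably must reject it
  res <- attapriori(net, uniform_prior(c(0L, 1L, 1L), 0.9), mode = "collect_all",
                    criteria = attractor_criteria(required_values = c(x1 = 1L)))
  hits <- res$attractors[res$hits]
  expect_identical(attractor_keys(hits), "101")
  # the "sometimes" variant accepts the oscillating cycle too
  res2 <- attapriori(net, uniform_prior(c(0L, 1L, 1L), 0.9), mode = "collect_all",
                     criteria = attractor_criteria(required_values = c(x1 = 1L),
                                                   match = "sometimes"))
  expect_identical(sort(attractor_keys(res2$attractors[res2$hits])),
                   c("011|100", "101"))
  expect_error(
    attapriori(net, uniform_prior(c(0L, 0L, 0L), 0.9),
               criteria = attractor_criteria(required_values = c(zz = 1L))),
    "unknown node")
})

test_that("trial and time limits terminate with the right reason", {
  net <- generate_nk(12, 2, seed = 5)
  res <- attapriori(net, uniform_prior(rep(0L, 12), 0.8),
                    criteria = attractor_criteria(period_min = 10^6),
                    max_trials = 37)
  expect_equal(res$trials_used, 37)
  expect_identical(res$termination_reason, "trial_limit")
})

test_that("truncated trajectories count as failed trials", {
  net <- example_net()
  res <- attapriori(net, uniform_prior(c(1L, 1L, 0L), 0.9), mode = "collect_all",
                    step_cap = 1L)
  expect_gt(res$truncated_trials, 0)
  expect_equal(res$trials_used, 8)
})

test_that("node-set mismatches are rejected", {
  net <- example_net()
  pr <- canonicalize_prior(c(0L, 0L), c(0.9, 0.9), nodes = c("a", "b"))
  expect_error(attapriori(net, pr), "differ")
})

test_that("search results summarize as a data frame", {
  net <- example_net()
  df <- as.data.frame(attapriori(net, uniform_prior(c(0L, 0L, 0L), 0.9),
                                 mode = "collect_all"))
  expect_identical(sort(names(df)),
                   sort(c("period", "transient", "states", "meets_criteria")))
  expect_equal(nrow(df), 3)
  expect_true(all(df$meets_criteria))
})
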