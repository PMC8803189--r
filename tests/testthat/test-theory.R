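test_that("prefix counts match direct binomial sums", {
  expect_equal(prefix_count(7, 0), 0)
  expect_equal(prefix_count(3, 2), 4)  # C(3,0) + C(3,1)
  expect_equal(prefix_count(40, 41), 2^40)
  expect_error(prefix_count(5, 7), "\\[0, n \\+ 1\\]")
})

test_that("worked-example expectations are exact", {
  expect_identical(expected_trials(1, 3/4), 5/4)
  expect_identical(expected_trials(2, 3/4), 7/4)
  expect_identical(expected_trials(2, 1/2), 5/2)  # uninformed-order limit
  expect_identical(expected_trials(1, 1/2), 3/2)
  for (n in c(1, 5, 40)) expect_identical(expected_trials(n, 1), 1)
})

test_that("binomial success probabilities used by E normalize exactly", {
  for (n in c(5, 17, 30)) for (p in c(0.6, 0.75, 0.9)) {
    k <- 0:n
    expect_equal(sum(choose(n, k) * p^(n - k) * (1 - p)^k), 1, tolerance = 1e-12)
  }
})

test_that("E agrees with a Monte-Carlo mean of trial indices", {
  n <- 10
  p <- 0.8
  reps <- 1e5
  set.seed(123)
  flips <- matrix(runif(reps * n) < 1 - p, reps, n)
  k <- rowSums(flips)
  S <- cumsum(c(0, choose(n, 0:n)))
  idx <- vapply(seq_len(reps), function(r) {
    sig <- which(rev(flips[r, ]))  - 1L  # significances of flipped bits
    S[k[r] + 1] + 1 + sum(choose(sort(sig), seq_len(k[r])))
  }, 0)
  # the arithmetic above is the independent oracle; spot-check it against
  # the package's ranking on a subsample
  sub <- sample(reps, 100)
  for (r in sub) {
    target <- rep(0L, n)
    guess <- as.integer(flips[r, ])
    expect_equal(trial_index_of_target(uniform_prior(guess, p), target), idx[r])
  }
  se <- sd(idx) / sqrt(reps)
  expect_lt(abs(mean(idx) - expected_trials(n, p)), 3 * se)
})

test_that("E decreases in p and stays within [1, 2^n]", {
  for (n in c(3, 10, 25)) {
    ps <- c(0.55, 0.6, 0.7, 0.8, 0.9, 0.99, 1)
    es <- vapply(ps, function(p) expected_trials(n, p), 0)
    expect_true(all(diff(es) < 0))
    expect_true(all(es >= 1 & es <= 2^n))
  }
})

test_that("log-domain evaluation matches direct evaluation where both work", {
  for (n in c(30, 100, 400)) for (p in c(0.7, 0.9)) {
    direct <- log(expected_trials(n, p))
    expect_equal(attapriori:::logsumexp(c(direct)), direct)
    expect_equal(expected_trials(n, p, log = TRUE), direct, tolerance = 1e-9)
  }
  # large-n path returns finite logs where the direct sum would overflow
  expect_true(is.finite(expected_trials(2000, 0.7, log = TRUE)))
  expect_equal(expected_trials(2000, 0.7, log = TRUE) / 2000, log(1.9165),
               tolerance = 0.01)
})

test_that("the complexity base matches the printed constants", {
  b7 <- complexity_base(0.7)
  b9 <- complexity_base(0.9)
  expect_equal(b7$base_3dp, 1.917)
  expect_equal(b9$base_3dp, 1.600)
  expect_equal(b9$alpha_star, 0.25)
  b5 <- complexity_base(0.5)
  expect_equal(b5$alpha_star, 0.5)
  expect_equal(b5$beta, 2)
  expect_equal(b5$base, 2)
  expect_error(complexity_base(0.4), "\\[0.5, 1\\)")
})

test_that("f(alpha*) maximizes f over the open interval and decreases in p", {
  alphas <- seq(1e-4, 0.5 - 1e-4, length.out = 1000)
  for (p in c(0.6, 0.7, 0.8, 0.9)) {
    f <- function(a) p^(1 - a) * (1 - p)^a * ((1/a)^a * (1/(1-a))^(1-a))^2
    expect_gte(complexity_base(p)$base + 1e-12, max(f(alphas)))
  }
  bases <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99), function(p)
    complexity_base(p)$base, 0)
  expect_true(all(diff(bases) < 0))
  expect_true(all(bases > 1 & bases <= 2 + 1e-12))
})

test_that("naive ratios reproduce the printed comparison", {
  expect_equal(signif(naive_ratio(100), 3), 0.00693)
  expect_equal(signif(naive_ratio(200), 4), 0.1201)
  expect_equal(signif(naive_ratio(500), 5), 6397.4)
  expect_equal(signif(naive_ratio(1000), 4), 2.558e12)
  expect_equal(naive_ratio(1), 2 / 1.917, tolerance = 1e-12)
  expect_true(is.finite(log(naive_ratio(10^6))) || naive_ratio(10^6) > 0)
})

test_that("the envelope dominates E and scales as ln f per node", {
  expect_gte(theoretical_trial_bound(40, 0.7), expected_trials(40, 0.7))
  expect_gte(theoretical_trial_bound(40, 0.9), expected_trials(40, 0.9))
  lb <- vapply(c(10, 20, 40), function(n)
    theoretical_trial_bound(n, 0.8, log = TRUE) - 2 * log(n), 0)
  expect_equal(diff(lb) / c(10, 20), rep(log(complexity_base(0.8)$base), 2))
  expect_lt(theoretical_trial_bound(30, 0.9), theoretical_trial_bound(30, 0.7))
})

test_that("a single envelope constant covers E across n and p", {
  ratios <- c()
  for (n in seq(5, 30, by = 5)) for (p in c(0.6, 0.7, 0.8, 0.9))
    ratios <- c(ratios, expected_trials(n, p) / theoretical_trial_bound(n, p))
  expect_lt(max(ratios), 1)  # constant 1 already suffices on this range
})

test_that("the semi-informed envelope interpolates between the extremes", {
  expect_equal(semi_informed_bound(15, 0, 0.8),
               theoretical_trial_bound(15, 0.8))
  expect_equal(semi_informed_bound(15, 10, 0.8, log = TRUE),
               semi_informed_bound(15, 5, 0.8, log = TRUE) + 5 * log(2))
  for (p in c(0.6, 0.8, 0.95)) {
    n1 <- 20; n2 <- 10
    expect_lt(semi_informed_bound(n1, n2, p, log = TRUE),
              (n1 + n2) * log(2) + 2 * log(n1))
  }
})
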