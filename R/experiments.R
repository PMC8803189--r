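# Benchmark harnesses: trial counts vs theory, trajectory lengths, and
# guided-vs-random total search cost, plus the scenario sweep used for
# biological models.

#' Trial-count benchmark against the analytic expectation
#'
#' For each network size and confidence: a random N-K network is generated,
#' an attractor is located by simulating from a random state, and one of its
#' states becomes the target.  Each replicate perturbs the target bitwise
#' with retention probability `p` to form the guess and computes the trial
#' index at which the enumeration would examine the target — in closed form
#' via [trial_index_of_target()], which is mathematically identical to
#' running the search with the "stop when the start vector equals the
#' target" counting rule (the count depends only on the guess–target flip
#' pattern).  Means are reported next to the exact expectation `E(n, p)` and
#' the envelope.
#'
#' @param n_values network sizes.
#' @param p_values uniform confidences in (0.5, 1].
#' @param replicates guesses drawn per (n, p) cell (default 1000).
#' @param k indegree of the generated networks (default 2).
#' @param seed master seed.
#' @return data frame: `n`, `p`, `replicates`, `mean_trials`, `se_trials`,
#'   `expected` (exact `E(n, p)`), `theory_envelope`, `seed`.
#' @export
run_trials_experiment <- function(n_values, p_values, replicates = 1000L,
                                  k = 2L, seed = 1L) {
  rows <- list()
  cell <- 0L
  for (n in n_values) for (p in p_values) {
    cell <- cell + 1L
    net <- generate_nk(n, k, seed = derive_seed(seed, cell))
    start <- random_state(n, seed = derive_seed(seed, cell) + 1L)
    traj <- simulate_to_attractor(net, start)
    target <- extract_attractor(traj)$cycle[[1L]]
    idx <- with_seed(derive_seed(seed, cell) + 2L, {
      vapply(seq_len(replicates), function(r) {
        guess <- perturb_state(target, p)
        trial_index_of_target(uniform_prior(guess, p), target)
      }, 0)
    })
    rows[[cell]] <- data.frame(
      n = n, p = p, replicates = replicates,
      mean_trials = mean(idx),
      se_trials = stats::sd(idx) / sqrt(replicates),
      expected = expected_trials(n, p),
      theory_envelope = if (p < 1) theoretical_trial_bound(n, p) else NA_real_,
      seed = seed)
  }
  do.call(rbind, rows)
}

#' Trajectory-length benchmark
#'
#' Per network size: fresh seeded random N-K networks simulated from random
#' initial states; the transient length (steps before entering the cycle,
#' cycle excluded) and the period are averaged separately.  Replicates that
#' hit the step cap are counted and excluded from the means.
#'
#' @param n_values network sizes.
#' @param k indegree (default 2).
#' @param replicates trajectories per size (one fresh network each,
#'   default 100).
#' @param seed master seed.
#' @param step_cap per-trajectory step bound (default `100 * n`).
#' @return data frame: `n`, `replicates`, `mean_transient`, `se_transient`,
#'   `mean_period`, `truncated`, `seed`.
#' @export
run_trajectory_length_experiment <- function(n_values = c(5, 10, 20, 50, 100),
                                             k = 2L, replicates = 100L,
                                             seed = 1L, step_cap = NULL) {
  rows <- list()
  for (ni in seq_along(n_values)) {
    n <- n_values[ni]
    cap <- if (is.null(step_cap)) 100L * n else step_cap
    transients <- numeric(0)
    periods <- numeric(0)
    truncated <- 0L
    for (r in seq_len(replicates)) {
      s <- derive_seed(seed, ni * 100000L + r)
      net <- generate_nk(n, k, seed = s)
      start <- random_state(n, seed = s + 1L)
      traj <- simulate_to_attractor(net, start, step_cap = cap)
      if (traj$truncated) { truncated <- truncated + 1L; next }
      att <- extract_attractor(traj)
      transients <- c(transients, att$transient)
      periods <- c(periods, att$period)
    }
    rows[[ni]] <- data.frame(
      n = n, replicates = replicates,
      mean_transient = mean(transients),
      se_transient = stats::sd(transients) / sqrt(length(transients)),
      mean_period = mean(periods),
      truncated = truncated, seed = seed)
  }
  do.call(rbind, rows)
}

# Restart from the stream (guided) or from uniform random states until the
# target attractor is reached; returns total transient steps (cycles
# excluded) over all trials, or NA if the restart cap is hit.
search_total_steps <- function(net, target_key, starts, cnet, step_cap,
                               max_restarts) {
  total <- 0
  for (trial in seq_len(max_restarts)) {
    v <- starts(trial)
    if (is.null(v)) return(NA_real_)
    traj <- simulate_to_attractor(net, v, step_cap = step_cap, compiled = cnet)
    if (traj$truncated) { total <- total + length(traj$states) - 1L; next }
    att <- extract_attractor(traj)
    total <- total + att$transient
    if (attractor_key(att) == target_key) return(total)
  }
  NA_real_
}

#' Guided-vs-random total trajectory length until the target attractor
#'
#' For each network size: a target attractor is fixed per seeded network
#' (found by simulation from a random state); the guided method restarts
#' from the prior-ordered stream around a perturbed guess, the random
#' method from uniform random states, each until the canonical target is
#' reached; both sum transient steps (cycles excluded).
#'
#' @param n_values network sizes.
#' @param p confidence of the guided prior (default 0.9).
#' @param replicates experiments per size (default 100).
#' @param k indegree (default 2).
#' @param seed master seed.
#' @param max_restarts per-experiment restart cap; capped runs are excluded
#'   from the means and counted in `capped_*`.
#' @return data frame with per-size means and standard errors of both
#'   methods' total transient steps.
#' @export
run_comparison_experiment <- function(n_values = c(10, 20, 30, 40), p = 0.9,
                                      replicates = 100L, k = 2L, seed = 1L,
                                      max_restarts = 100000L) {
  rows <- list()
  for (ni in seq_along(n_values)) {
    n <- n_values[ni]
    apriori_tot <- numeric(0)
    random_tot <- numeric(0)
    capped_a <- 0L
    capped_r <- 0L
    for (r in seq_len(replicates)) {
      s <- derive_seed(seed, ni * 1000000L + r)
      net <- generate_nk(n, k, seed = s)
      cnet <- compile_network(net)
      start <- random_state(n, seed = s + 1L)
      target <- extract_attractor(simulate_to_attractor(net, start,
                                                        compiled = cnet))
      tkey <- attractor_key(target)
      guess <- perturb_state(target$cycle[[1L]], p, seed = s + 2L)
      it <- start_vector_iterator(uniform_prior(guess, p), seed = s + 3L)
      ta <- search_total_steps(net, tkey, function(trial) it$next_state(),
                               cnet, 100L * n, max_restarts)
      rnd_states <- local({
        counter <- 0L
        function(trial) {
          counter <<- counter + 1L
          random_state(n, seed = derive_seed(s + 4L, counter))
        }
      })
      tr <- search_total_steps(net, tkey, rnd_states, cnet, 100L * n,
                               max_restarts)
      if (is.na(ta)) capped_a <- capped_a + 1L else
        apriori_tot <- c(apriori_tot, ta)
      if (is.na(tr)) capped_r <- capped_r + 1L else
        random_tot <- c(random_tot, tr)
    }
    rows[[ni]] <- data.frame(
      n = n, p = p, replicates = replicates,
      mean_total_steps_apriori = mean(apriori_tot),
      se_apriori = stats::sd(apriori_tot) / sqrt(length(apriori_tot)),
      mean_total_steps_random = mean(random_tot),
      se_random = stats::sd(random_tot) / sqrt(length(random_tot)),
      capped_apriori = capped_a, capped_random = capped_r, seed = seed)
  }
  do.call(rbind, rows)
}

#' Scenario sweep: fixed nodes, ON/OFF fill, confidence grid
#'
#' The protocol used for biological models: some nodes carry known values
#' (confidence 1); every remaining node is guessed at the scenario fill
#' value (all 0 for OFF, all 1 for ON) with a swept confidence; each
#' (scenario, confidence) combination is searched in collect-all mode under
#' the given limits.
#'
#' @param net a [boolean_network()].
#' @param fixed named 0/1 vector of known node values (may be empty).
#' @param scenarios subset of `c("off", "on")`.
#' @param confidences confidences for the filled nodes (values in (0.5, 1]).
#' @param criteria an [attractor_criteria()].
#' @param max_trials,time_limit,step_cap search limits (see [attapriori()]).
#' @param seed master seed.
#' @return data frame, one row per (scenario, confidence, attractor):
#'   columns `scenario`, `confidence`, `trials_used`, `termination_reason`,
#'   `period`, `states`, `meets_criteria`.
#' @export
run_scenario_sweep <- function(net, fixed = integer(0),
                               scenarios = c("off", "on"),
                               confidences = c(0.7, 0.8, 0.9, 1),
                               criteria = attractor_criteria(),
                               max_trials = 1000L, time_limit = NULL,
                               step_cap = NULL, seed = 1L) {
  n <- network_size(net)
  if (length(fixed) > 0L) {
    missing <- setdiff(names(fixed), net$nodes)
    if (length(missing) > 0L)
      stop("fixed assignment names node(s) not in the network: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(step_cap)) step_cap <- 100L * n
  fill_idx <- which(!(net$nodes %in% names(fixed)))
  rows <- list()
  run <- 0L
  for (sc in scenarios) for (conf in confidences) {
    run <- run + 1L
    guess <- integer(n)
    prob <- rep(1, n)
    if (length(fixed) > 0L)
      guess[match(names(fixed), net$nodes)] <- as.integer(fixed)
    guess[fill_idx] <- if (sc == "on") 1L else 0L
    prob[fill_idx] <- conf
    prior <- canonicalize_prior(guess, prob, nodes = net$nodes)
    res <- attapriori(net, prior, criteria = criteria, mode = "collect_all",
                      step_cap = step_cap, max_trials = max_trials,
                      time_limit = time_limit, seed = derive_seed(seed, run))
    df <- as.data.frame(res)
    if (nrow(df) == 0L)
      df <- data.frame(period = NA_integer_, transient = NA_integer_,
                       states = NA_character_, meets_criteria = NA)
    df$scenario <- sc
    df$confidence <- conf
    df$trials_used <- res$trials_used
    df$termination_reason <- res$termination_reason
    rows[[run]] <- df[, c("scenario", "confidence", "trials_used",
                          "termination_reason", "period", "states",
                          "meets_criteria")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
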