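# Random N-K networks, prior-perturbed guesses, AND/OR functional mutants
# and random states: the inputs of the benchmark experiments.
#
# All generators are pure functions of (config, seed): they run under a
# saved/restored RNG state, so they neither depend on nor disturb the
# caller's random stream.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a module seed from a master seed
#'
#' Experiment harnesses derive one seed per (operation, index) by fixed
#' labeled offsets so a whole run is reproducible from a single master seed.
#'
#' @param seed master seed, `offset` non-negative integer label.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset)
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483647)

#' Generate a random N-K Boolean network
#'
#' Every node receives exactly `k` distinct input nodes drawn uniformly and
#' an independent uniformly random (non-constant) truth table over the
#' `2^k` input rows, realized as an expression by full minterm expansion.
#' Constant truth tables are resampled so that each realized rule references
#' all `k` declared inputs (keeping the structural indegree exact); the
#' resampling is symmetric in 0/1, so table entries remain fair coins.
#'
#' @param n node count, `k` exact indegree (`1 <= k <= n`, or `k <= n - 1`
#'   when self-inputs are disallowed).
#' @param seed integer seed; equal seeds give identical networks.
#' @param allow_self_inputs may a node be its own input (default TRUE).
#' @return a [boolean_network()] with nodes `x1..xn`.
#' @export
generate_nk <- function(n, k, seed = NULL, allow_self_inputs = TRUE) {
  if (k < 1 || k > n) stop("need 1 <= k <= n", call. = FALSE)
  if (!allow_self_inputs && k > n - 1)
    stop("k must be <= n - 1 when self-inputs are disallowed", call. = FALSE)
  with_seed(seed, {
    nodes <- paste0("x", seq_len(n))
    rules <- vector("list", n)
    for (i in seq_len(n)) {
      pool <- if (allow_self_inputs) seq_len(n) else setdiff(seq_len(n), i)
      inp <- nodes[sample(pool, k)]
      repeat {
        tab <- stats::rbinom(2^k, 1L, 0.5)
        if (any(tab == 1L) && any(tab == 0L)) break
      }
      rules[[i]] <- minterm_expression(inp, tab)
    }
    boolean_network(nodes, rules)
  })
}

# OR of full minterms (each AND term carries all k literals), so the
# expression references exactly the declared inputs; row r of `tab` is the
# assignment with the first input as most-significant bit.
minterm_expression <- function(inputs, tab) {
  k <- length(inputs)
  ones <- which(tab == 1L)
  terms <- lapply(ones, function(r) {
    bits <- bitwAnd(bitwShiftR(r - 1L, (k - 1L):0L), 1L)
    lits <- lapply(seq_len(k), function(j)
      if (bits[j] == 1L) bn_var(inputs[j]) else bn_not(bn_var(inputs[j])))
    bn_and(lits)
  })
  bn_or(terms)
}

#' Perturb a state bitwise according to a prior probability
#'
#' Each bit is independently flipped with probability `1 - p`: the resulting
#' vector is a draw of the guess a scientist with confidence `p` per bit
#' would produce around the true state.
#'
#' @param state 0/1 vector, `p` per-bit retention probability in `[0, 1]`.
#' @param seed integer seed or NULL.
#' @return a 0/1 vector of the same length.
#' @export
perturb_state <- function(state, p, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    flip <- stats::runif(length(state)) < 1 - p
    out <- as.integer(state)
    out[flip] <- 1L - out[flip]
    out
  })
}

#' Random global state (fair coin per node)
#'
#' @param n number of nodes, `seed` integer seed or NULL.
#' @export
random_state <- function(n, seed = NULL)
  with_seed(seed, stats::rbinom(n, 1L, 0.5))

#' Swap AND/OR operators at random (functional mutants)
#'
#' Walks every expression tree and independently relabels each operator node
#' of the targeted kind with probability `rate`: `"and2or"` models
#' functional promiscuity, `"or2and"` functional restriction.  Inputs,
#' negations and tree structure are untouched; the input network is not
#' modified.
#'
#' @param net a [boolean_network()].
#' @param rate swap probability per operator node in `[0, 1]`.
#' @param direction `"and2or"` or `"or2and"`.
#' @param seed integer seed or NULL.
#' @return a new `boolean_network`.
#' @export
mutate_functions <- function(net, rate, direction = c("and2or", "or2and"),
                             seed = NULL) {
  direction <- match.arg(direction)
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  from <- if (direction == "and2or") "and" else "or"
  to <- if (direction == "and2or") "or" else "and"
  mutate_expr <- function(e) {
    switch(e$type,
      const = ,
      var = e,
      not = { e$arg <- mutate_expr(e$arg); e },
      and = ,
      or = {
        e$args <- lapply(e$args, mutate_expr)
        if (e$type == from && stats::runif(1) < rate) e$type <- to
        e
      })
  }
  with_seed(seed, boolean_network(net$nodes, lapply(net$rules, mutate_expr)))
}
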