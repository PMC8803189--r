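# Trajectory simulation, attractor extraction and a brute-force enumeration
# oracle for small networks.

#' Simulate a trajectory until the first state repeat
#'
#' Iterates the synchronous update from `start` until a state repeats
#' (closing an attractor cycle) or until `step_cap` updates have been
#' applied.  Cycle detection keeps a map from visited state to its time
#' index, so the position `t'` of the first repeat is found in one pass and
#' memory stays proportional to the trajectory length.
#'
#' @param net a [boolean_network()].
#' @param start initial state (0/1 vector in node order).
#' @param step_cap maximum number of updates before giving up (default
#'   `100 * n`; trajectories of practical networks are far shorter, but a cap
#'   keeps the per-trial work bounded).
#' @param compiled optional pre-compiled network (internal reuse).
#' @return an object of class `bn_trajectory`: list with `states` (the
#'   pairwise-distinct visited states `x(0)..x(T)`), `cycle_entry` (1-based
#'   index `t'+1` of the state the trajectory re-enters, or `NA` when
#'   truncated), and `truncated`.
#' @export
simulate_to_attractor <- function(net, start, step_cap = 100L * network_size(net),
                                  compiled = NULL) {
  if (step_cap < 1L) stop("step_cap must be >= 1", call. = FALSE)
  n <- network_size(net)
  start <- check_state(start, n)
  cnet <- if (is.null(compiled)) compile_network(net) else compiled
  seen <- new.env(parent = emptyenv())
  states <- vector("list", 64L)
  cur <- start
  t <- 0L
  assign(state_key(cur), 1L, envir = seen)
  states[[1L]] <- cur
  cycle_entry <- NA_integer_
  while (t < step_cap) {
    nxt <- step_compiled(cnet, cur)
    t <- t + 1L
    key <- state_key(nxt)
    hit <- get0(key, envir = seen, inherits = FALSE)
    if (!is.null(hit)) { cycle_entry <- hit; break }
    if (t + 1L > length(states)) states <- c(states, vector("list", length(states)))
    states[[t + 1L]] <- nxt
    assign(key, t + 1L, envir = seen)
    cur <- nxt
  }
  structure(
    list(states = states[seq_len(t + (is.na(cycle_entry)))],
         cycle_entry = cycle_entry,
         truncated = is.na(cycle_entry)),
    class = "bn_trajectory")
}

#' Extract the canonical attractor from a trajectory
#'
#' The cycle is rotated to begin at its numerically smallest state (node
#' `x_n` least significant), so two trajectories entering the same cycle at
#' different phases yield identical attractors.
#'
#' @param traj a `bn_trajectory` from [simulate_to_attractor()].
#' @return an object of class `bn_attractor`: list with `cycle` (list of
#'   states), `period`, `transient` (steps before entering the cycle,
#'   excluding the cycle itself) and `canonical = TRUE`.
#' @export
extract_attractor <- function(traj) {
  if (traj$truncated)
    stop("trajectory was truncated before reaching an attractor", call. = FALSE)
  cycle <- traj$states[traj$cycle_entry:length(traj$states)]
  structure(
    c(canonicalize_cycle(cycle), list(transient = traj$cycle_entry - 1L)),
    class = "bn_attractor")
}

canonicalize_cycle <- function(cycle) {
  p <- length(cycle)
  best <- 1L
  for (i in seq_len(p)[-1L]) if (state_less(cycle[[i]], cycle[[best]])) best <- i
  cycle <- cycle[c(seq(best, p), if (best > 1L) seq(1L, best - 1L))]
  list(cycle = cycle, period = p, canonical = TRUE)
}

attractor_key <- function(att)
  paste(vapply(att$cycle, state_key, ""), collapse = "|")

#' @export
print.bn_attractor <- function(x, ...) {
  cat(sprintf("%s attractor, period %d%s\n",
              if (x$period == 1L) "Point" else "Periodic", x$period,
              if (!is.null(x$transient))
                sprintf(" (transient %d)", x$transient) else ""))
  for (s in x$cycle) cat(" ", state_key(s), "\n")
  invisible(x)
}

#' @export
as.data.frame.bn_attractor <- function(x, ...) {
  data.frame(period = x$period,
             transient = if (is.null(x$transient)) NA_integer_ else x$transient,
             states = paste(vapply(x$cycle, state_key, ""), collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Enumerate all attractors of a small network exhaustively
#'
#' Walks every one of the `2^n` states with memoized basin assignment, so
#' each state is visited a bounded number of times.  Serves as the oracle
#' that the prior-guided search is tested against.
#'
#' @param net a [boolean_network()].
#' @param n_limit refuse networks larger than this (default 20).
#' @return list of canonical `bn_attractor`s (discovery order, `transient`
#'   absent); attribute `basin_sizes` gives each attractor's basin size
#'   (they sum to `2^n`).
#' @export
enumerate_all_attractors <- function(net, n_limit = 20L) {
  n <- network_size(net)
  if (n > n_limit)
    stop(sprintf("network has %d nodes; exhaustive enumeration limited to %d",
                 n, n_limit), call. = FALSE)
  cnet <- compile_network(net)
  basin <- new.env(parent = emptyenv())  # state key -> attractor id
  attractors <- list()
  basin_sizes <- integer(0)
  for (v in 0:(2^n - 1)) {
    cur <- state_from_integer(v, n)
    if (!is.null(get0(state_key(cur), envir = basin, inherits = FALSE)))
      next  # assigned (and counted) when first reached on an earlier path
    path <- list(cur)
    path_pos <- new.env(parent = emptyenv())
    assign(state_key(cur), 1L, envir = path_pos)
    id <- NA_integer_
    repeat {
      nxt <- step_compiled(cnet, cur)
      key <- state_key(nxt)
      known <- get0(key, envir = basin, inherits = FALSE)
      if (!is.null(known)) { id <- known; break }
      onpath <- get0(key, envir = path_pos, inherits = FALSE)
      if (!is.null(onpath)) {
        att <- structure(canonicalize_cycle(path[onpath:length(path)]),
                         class = "bn_attractor")
        attractors[[length(attractors) + 1L]] <- att
        basin_sizes <- c(basin_sizes, 0L)
        id <- length(attractors)
        break
      }
      path[[length(path) + 1L]] <- nxt
      assign(key, length(path), envir = path_pos)
      cur <- nxt
    }
    for (s in path) assign(state_key(s), id, envir = basin)
    basin_sizes[id] <- basin_sizes[id] + length(path)
  }
  attr(attractors, "basin_sizes") <- basin_sizes
  attractors
}
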