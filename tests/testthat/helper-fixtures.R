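# Shared fixtures, all built in code.

# The three-node worked example: two point attractors and one period-2 cycle.
example_net <- function() {
  parse_network("targets, factors
x1, x3
x2, x1 & ! x3
x3, x1 & ! x2")
}

# Independent full state-transition-graph enumeration: follow every state's
# successor map and harvest the cycles (no shared code with the memoized
# basin walker beyond step_network itself).
oracle_attractor_keys <- function(net) {
  n <- network_size(net)
  succ <- vapply(0:(2^n - 1), function(v) {
    state_to_integer(step_network(net, state_from_integer(v, n)))
  }, 0)
  keys <- character(0)
  for (v in 0:(2^n - 1)) {
    # walk 2^n steps to be certainly inside the cycle, then read it off
    cur <- v
    for (i in seq_len(2^n)) cur <- succ[cur + 1]
    cyc <- cur
    cycle <- numeric(0)
    repeat {
      cycle <- c(cycle, cyc)
      cyc <- succ[cyc + 1]
      if (cyc == cur) break
    }
    rot <- which.min(cycle)
    cycle <- c(cycle[rot:length(cycle)], cycle[seq_len(rot - 1)])
    keys <- c(keys, paste(vapply(cycle, function(x)
      paste(state_from_integer(x, n), collapse = ""), ""), collapse = "|"))
  }
  sort(unique(keys))
}

attractor_keys <- function(atts)
  sort(vapply(atts, function(a)
    paste(vapply(a$cycle, function(s) paste(s, collapse = ""), ""),
          collapse = "|"), ""))

# Period-2 attractor over 5 nodes used by the annotation tests:
# states (1,0,1,0,1) and (0,1,1,0,1); built directly, not simulated.
make_attractor <- function(states) {
  cycle <- lapply(states, as.integer)
  rot <- 1L
  for (i in seq_along(cycle)[-1L])
    if (paste(cycle[[i]], collapse = "") < paste(cycle[[rot]], collapse = ""))
      rot <- i
  cycle <- cycle[c(seq(rot, length(cycle)), if (rot > 1L) seq_len(rot - 1L))]
  structure(list(cycle = cycle, period = length(cycle), canonical = TRUE),
            class = "bn_attractor")
}
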