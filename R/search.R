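# The prior-guided attractor search.

#' Acceptance criteria for a detected attractor
#'
#' @param period_min,period_max optional period bounds.
#' @param required_values optional named 0/1 vector; each named node must
#'   hold its value in every cycle state (`match = "always"`, the stable-
#'   signature rule) or in at least one cycle state (`match = "sometimes"`).
#' @param match stability rule for `required_values`.
#' @return an `attractor_criteria` object; the default accepts any attractor.
#' @export
attractor_criteria <- function(period_min = NULL, period_max = NULL,
                               required_values = NULL,
                               match = c("always", "sometimes")) {
  match <- match.arg(match)
  if (!is.null(period_min) && !is.null(period_max) && period_min > period_max)
    stop("period_min must not exceed period_max", call. = FALSE)
  structure(list(period_min = period_min, period_max = period_max,
                 required_values = required_values, match = match,
                 accept_any = is.null(period_min) && is.null(period_max) &&
                   is.null(required_values)),
            class = "attractor_criteria")
}

criteria_met <- function(att, criteria, nodes) {
  if (criteria$accept_any) return(TRUE)
  if (!is.null(criteria$period_min) && att$period < criteria$period_min) return(FALSE)
  if (!is.null(criteria$period_max) && att$period > criteria$period_max) return(FALSE)
  rv <- criteria$required_values
  if (!is.null(rv)) {
    idx <- match(names(rv), nodes)
    if (anyNA(idx))
      stop("required_values names unknown node(s): ",
           paste(names(rv)[is.na(idx)], collapse = ", "), call. = FALSE)
    mat <- do.call(rbind, att$cycle)[, idx, drop = FALSE]
    ok <- if (criteria$match == "always")
      all(t(mat) == as.integer(rv)) else
      all(apply(mat, 2, function(col) any(col == 1L))[as.integer(rv) == 1L]) &&
      all(apply(mat, 2, function(col) any(col == 0L))[as.integer(rv) == 0L])
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Prior-guided attractor detection
#'
#' Runs trajectories from candidate start vectors in decreasing prior
#' likelihood (see [start_vector_iterator()]) and tests each reached
#' attractor against the criteria.  `mode = "first_hit"` stops at the first
#' attractor meeting the criteria; `mode = "collect_all"` keeps searching
#' until the stream, the trial budget or the time budget is exhausted,
#' deduplicating attractors by canonical identity.
#'
#' @param net a [boolean_network()].
#' @param prior a [canonicalize_prior()] object over the same nodes.
#' @param criteria an [attractor_criteria()].
#' @param mode `"first_hit"` or `"collect_all"`.
#' @param step_cap per-trajectory step bound; a trajectory hitting the cap
#'   counts as a failed trial.
#' @param max_trials optional trial budget (exact).
#' @param time_limit optional wall-clock budget in seconds, checked between
#'   trials.
#' @param thresholds optional per-class flip caps (see
#'   [start_vector_iterator()]).
#' @param seed seed for the uninformed-bit order.
#' @return an `attapriori_result`: `attractors` (deduplicated, discovery
#'   order), `hits` (indices of attractors meeting the criteria),
#'   `trials_used`, `truncated_trials`, `total_transient_steps` (transient
#'   steps summed over all trials, cycles excluded) and
#'   `termination_reason` (`criteria_met`, `exhausted`, `trial_limit` or
#'   `time_limit`).
#' @examples
#' net <- parse_network("targets, factors\nx1, x3\nx2, x1 & ! x3\nx3, x1 & ! x2")
#' res <- attapriori(net, uniform_prior(c(0, 0, 0), 0.9), mode = "collect_all")
#' summary(res)
#' @export
attapriori <- function(net, prior,
                       criteria = attractor_criteria(),
                       mode = c("first_hit", "collect_all"),
                       step_cap = 100L * network_size(net),
                       max_trials = NULL, time_limit = NULL,
                       thresholds = NULL, seed = 1L) {
  mode <- match.arg(mode)
  n <- network_size(net)
  if (nrow(prior) != n)
    stop("prior and network node sets differ in size", call. = FALSE)
  if (!isTRUE(attr(prior, "auto_names")) && !all(prior$node == net$nodes))
    stop("prior and network node sets differ", call. = FALSE)
  cnet <- compile_network(net)
  it <- start_vector_iterator(prior, thresholds = thresholds, seed = seed)
  seen <- new.env(parent = emptyenv())
  attractors <- list()
  hits <- integer(0)
  trials <- 0
  truncated <- 0
  total_transient <- 0
  reason <- "exhausted"
  t0 <- proc.time()[["elapsed"]]
  repeat {
    if (!is.null(max_trials) && trials >= max_trials) { reason <- "trial_limit"; break }
    if (!is.null(time_limit) && proc.time()[["elapsed"]] - t0 > time_limit) {
      reason <- "time_limit"; break
    }
    v <- it$next_state()
    if (is.null(v)) { reason <- "exhausted"; break }
    trials <- trials + 1
    traj <- simulate_to_attractor(net, v, step_cap = step_cap, compiled = cnet)
    if (traj$truncated) {
      truncated <- truncated + 1
      total_transient <- total_transient + length(traj$states) - 1L
      next
    }
    att <- extract_attractor(traj)
    total_transient <- total_transient + att$transient
    key <- attractor_key(att)
    if (is.null(get0(key, envir = seen, inherits = FALSE))) {
      attractors[[length(attractors) + 1L]] <- att
      assign(key, length(attractors), envir = seen)
      if (criteria_met(att, criteria, net$nodes)) {
        hits <- c(hits, length(attractors))
        if (mode == "first_hit") { reason <- "criteria_met"; break }
      }
    }
  }
  structure(
    list(attractors = attractors, hits = hits, trials_used = trials,
         truncated_trials = truncated, total_transient_steps = total_transient,
         termination_reason = reason, mode = mode, nodes = net$nodes,
         seed = seed),
    class = "attapriori_result")
}

#' @export
print.attapriori_result <- function(x, ...) {
  cat(sprintf(
    "Prior-guided attractor search (%s): %d trial%s, %d attractor%s, %s\n",
    x$mode, x$trials_used, if (x$trials_used == 1) "" else "s",
    length(x$attractors), if (length(x$attractors) == 1) "" else "s",
    x$termination_reason))
  invisible(x)
}

#' @export
summary.attapriori_result <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Trials: %d (%d truncated), transient steps: %d, reason: %s\n",
              object$trials_used, object$truncated_trials,
              object$total_transient_steps, object$termination_reason))
  if (nrow(df) > 0) print(df)
  invisible(df)
}

#' @export
as.data.frame.attapriori_result <- function(x, ...) {
  if (length(x$attractors) == 0L)
    return(data.frame(period = integer(0), transient = integer(0),
                      meets_criteria = logical(0), states = character(0)))
  df <- do.call(rbind, lapply(x$attractors, as.data.frame))
  df$meets_criteria <- seq_len(nrow(df)) %in% x$hits
  df
}
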