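# Global states.
#
# A state is a plain integer vector of 0/1, position i holding the value of
# node x_i.  Its numeric view treats x_n as the least-significant bit, so
# within a Hamming-weight class numeric order equals the enumeration order
# used by the search (001 < 010 < 100 for n = 3).  For n beyond the double
# mantissa the numeric view is unavailable but all order comparisons fall
# back to lexicographic comparison on bits, which induces the same order.

check_state <- function(state, n) {
  state <- as.integer(state)
  if (length(state) != n)
    stop(sprintf("state has length %d but the network has %d nodes",
                 length(state), n), call. = FALSE)
  if (any(state != 0L & state != 1L))
    stop("state values must be 0 or 1", call. = FALSE)
  state
}

#' Convert between bit-vector and integer views of a state
#'
#' Node `x_n` is the least-significant bit.  Exact only while `2^n` fits the
#' double mantissa (`n <= 52`); `state_from_integer` enforces this.
#'
#' @param state integer 0/1 vector.
#' @param value non-negative number, `n` state length.
#' @return `state_to_integer`: a double; `state_from_integer`: a 0/1 vector.
#' @export
state_to_integer <- function(state) sum(state * 2^((length(state) - 1L):0L))

#' @rdname state_to_integer
#' @export
state_from_integer <- function(value, n) {
  if (n > 52L) stop("integer view exact only for n <= 52", call. = FALSE)
  if (value < 0 || value >= 2^n) stop("value out of range", call. = FALSE)
  as.integer(floor(value / 2^((n - 1L):0L)) %% 2)
}

state_key <- function(state) paste(state, collapse = "")

# TRUE when a < b in the numeric (x_n least-significant) order.
state_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}
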