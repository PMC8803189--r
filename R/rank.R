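# Combinatorial ranking of start vectors.
#
# With a single informed class over m flippable bits, candidate start
# vectors are ordered primarily by Hamming distance k from the guess and,
# within a weight class, by increasing numeric value of the flip pattern
# (node x_n least significant).  The trial index of a vector with flip set
# {c_1 < ... < c_k} (c_j = 0-based bit significances) is then
#     S(m, k) + 1 + sum_j choose(c_j, j),
# the prefix count of lighter vectors plus the colexicographic rank of the
# flip set (the combinatorial number system).  All arithmetic is O(m) and
# exact while the values fit the double mantissa (2^53, i.e. any m <= 52).

#' Prefix count S(n, k): number of bit vectors with fewer than k ones
#'
#' `S(n, k) = sum_{i < k} choose(n, i)`; `S(n, 0) = 0` and
#' `S(n, n + 1) = 2^n`.
#'
#' @param n vector length, `k` weight bound with `0 <= k <= n + 1`.
#' @return a double (exact below 2^53).
#' @export
prefix_count <- function(n, k) {
  if (k < 0 || k > n + 1) stop("k must lie in [0, n + 1]", call. = FALSE)
  if (k == 0) return(0)
  sum(choose(n, 0:(k - 1)))
}

# colex rank (1-based) of a flip set given as 0-based significances.
colex_rank <- function(sigs) {
  k <- length(sigs)
  if (k == 0L) return(1)
  1 + sum(choose(sort(sigs), seq_len(k)))
}

# inverse: 0-based significances of the flip set with 1-based colex rank r
# among weight-k subsets of {0, ..., m-1}.
colex_unrank <- function(r, k, m) {
  if (k == 0L) return(integer(0))
  r <- r - 1
  sigs <- integer(k)
  for (j in k:1) {
    # largest c with choose(c, j) <= r
    c <- j - 1L
    while (c + 1L < m && choose(c + 1L, j) <= r) c <- c + 1L
    sigs[j] <- c
    r <- r - choose(c, j)
  }
  sigs
}

# For a single-informed-class prior: positions that may flip and their
# significances.  Probability-1 bits never flip; uninformed bits are not
# allowed here (they have no deterministic closed-form rank).
single_class_positions <- function(prior) {
  if (any(prior$uninformed))
    stop("closed-form ranking requires an informed prior (no p = 0.5 bits)",
         call. = FALSE)
  flippable <- which(prior$prob < 1)
  if (length(unique(prior$prob[flippable])) > 1L)
    stop("closed-form ranking requires a single informed confidence class",
         call. = FALSE)
  flippable
}

#' Trial index of a start vector under a single-class prior
#'
#' `rank_start_vector` returns the 1-based position at which the enumeration
#' emits `v`; `unrank_start_vector` is its inverse.  Both are computed
#' combinatorially (no enumeration).
#'
#' @param prior a [canonicalize_prior()] object with one informed confidence
#'   class (probability-1 bits allowed, uninformed bits not).
#' @param v a state; must agree with the guess on probability-1 bits.
#' @param index 1-based index in `[1, 2^m]`, `m` = number of flippable bits.
#' @return `rank_start_vector`: a double index; `unrank_start_vector`: a
#'   state vector.
#' @examples
#' pr <- uniform_prior(c(0, 0, 0), 0.75)
#' rank_start_vector(pr, c(0, 1, 0))   # 3
#' unrank_start_vector(pr, 3)
#' @export
rank_start_vector <- function(prior, v) {
  n <- nrow(prior)
  v <- check_state(v, n)
  pos <- single_class_positions(prior)
  fixed <- setdiff(seq_len(n), pos)
  if (any(v[fixed] != prior$guess[fixed]))
    stop("vector conflicts with a probability-1 bit; it is never examined",
         call. = FALSE)
  m <- length(pos)
  flipped <- pos[v[pos] != prior$guess[pos]]
  # significance of node i among the flippable bits: count of flippable
  # positions strictly after i (x_n least significant)
  sig <- vapply(flipped, function(i) sum(pos > i), 0L)
  prefix_count(m, length(flipped)) + colex_rank(sig)
}

#' @rdname rank_start_vector
#' @export
unrank_start_vector <- function(prior, index) {
  n <- nrow(prior)
  pos <- single_class_positions(prior)
  m <- length(pos)
  if (index < 1 || index > 2^m) stop("index out of range", call. = FALSE)
  k <- 0L
  while (prefix_count(m, k + 1L) < index) k <- k + 1L
  r <- index - prefix_count(m, k)
  sigs <- colex_unrank(r, k, m)
  v <- prior$guess
  # significance s corresponds to the (s+1)-th flippable position from the end
  flip_at <- pos[m - sigs]
  v[flip_at] <- 1L - v[flip_at]
  as.integer(v)
}

#' Closed-form trial index of a target state
#'
#' Returns the exact number of trials the search performs until the target
#' vector itself is examined, computed from the Hamming distance between
#' guess and target and the colexicographic rank of the flip set.  This is
#' the quantity whose expectation the complexity theory bounds, and it is
#' what the trial-count benchmark averages (means reach ~1e10 at n = 40, so
#' literal enumeration is not an option).
#'
#' @inheritParams rank_start_vector
#' @param target a state of the target attractor.
#' @return a double trial index (>= 1).
#' @export
trial_index_of_target <- function(prior, target) rank_start_vector(prior, target)
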