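# Lazy enumeration of start vectors in prior-likelihood order.
#
# Bits split by confidence: probability-1 bits never change; informed
# classes (0.5 < p < 1) are flipped in increasing total log-odds cost
# sum_c k_c * ln(p_c / (1 - p_c)); uninformed bits (p = 0.5) are enumerated
# innermost, completely, in a seeded pseudo-random order.  With a single
# informed class the order reduces to Hamming distance from the guess with
# numeric tie-break, matching the closed-form ranking.

# Deterministic small PRNG (Park-Miller), independent of R's global RNG so
# the stream never perturbs user simulations.
lcg_next <- function(x) (48271 * x) %% 2147483647

lcg_stream <- function(seed, k) {
  x <- (abs(seed) %% 2147483646) + 1
  out <- numeric(k)
  for (i in seq_len(k)) { x <- lcg_next(x); out[i] <- x }
  out
}

# Seeded bijection on j = 1..2^n2: permute bit positions, then XOR a mask.
# Complete and O(n2) per item; the order is pseudo-random, reproducible from
# (seed, block), and needs no stored permutation of size 2^n2.
uninformed_order_bits <- function(j, n2, seed, block) {
  draws <- lcg_stream(seed * 1000003 + block, 2L * n2)
  perm <- order(draws[seq_len(n2)])
  mask <- as.integer(draws[n2 + seq_len(n2)] %% 2)
  bits <- as.integer(floor((j - 1) / 2^((n2 - 1L):0L)) %% 2)
  bitwXor(bits[perm], mask)
}

# Iterator over per-class flip-count tuples (k_1, ..., k_h) in nondecreasing
# total cost, ties broken by fewer total flips then lexicographic order.
# Lazy best-first expansion so huge tuple spaces are never materialized.
tuple_iterator <- function(sizes, weights, thresholds) {
  h <- length(sizes)
  caps <- pmin(sizes, thresholds)
  frontier <- list(list(k = rep(0L, h), cost = 0))
  seen <- new.env(parent = emptyenv())
  assign(paste0("k", paste(rep(0L, h), collapse = ",")), TRUE, envir = seen)
  pop_best <- function() {
    best <- 1L
    for (i in seq_along(frontier)[-1L]) {
      a <- frontier[[i]]; b <- frontier[[best]]
      if (a$cost < b$cost - 1e-12 ||
          (abs(a$cost - b$cost) <= 1e-12 &&
           (sum(a$k) < sum(b$k) ||
            (sum(a$k) == sum(b$k) &&
             state_less(a$k, b$k))))) best <- i
    }
    out <- frontier[[best]]
    frontier[[best]] <<- NULL
    out
  }
  list(next_tuple = function() {
    if (length(frontier) == 0L) return(NULL)
    cur <- pop_best()
    for (c in seq_len(h)) {
      if (cur$k[c] < caps[c]) {
        nk <- cur$k
        nk[c] <- nk[c] + 1L
        key <- paste0("k", paste(nk, collapse = ","))
        if (is.null(get0(key, envir = seen, inherits = FALSE))) {
          assign(key, TRUE, envir = seen)
          frontier[[length(frontier) + 1L]] <<- list(k = nk, cost = sum(nk * weights))
        }
      }
    }
    cur$k
  })
}

# Iterator over weight-k subsets of a class's positions in colexicographic
# order on bit significance (= increasing numeric value of the flip
# pattern).  Yields 1-based indices into the class's significance-ordered
# position list; NULL when exhausted.
combo_iterator <- function(m, k) {
  cur <- NULL
  done <- FALSE
  list(next_combo = function() {
    if (done) return(NULL)
    if (is.null(cur)) {
      cur <<- if (k == 0L) integer(0) else seq_len(k)
      if (k == 0L) done <<- TRUE
      return(cur)
    }
    # colex successor: bump the first index that has room, reset those below
    j <- 1L
    while (j <= k) {
      lim <- if (j == k) m else cur[j + 1L] - 1L
      if (cur[j] < lim) break
      j <- j + 1L
    }
    if (j > k) { done <<- TRUE; return(NULL) }
    cur[j] <<- cur[j] + 1L
    if (j > 1L) cur[seq_len(j - 1L)] <<- seq_len(j - 1L)
    cur
  })
}

#' Iterate admissible start vectors in prior-likelihood order
#'
#' Returns a closure-based iterator producing each admissible start vector
#' exactly once: probability-1 bits never change; flip patterns over the
#' informed classes appear in nondecreasing total log-odds cost (per-class
#' flip counts optionally capped by `thresholds`); the `2^n2` assignments of
#' the uninformed bits are nested innermost in a seeded pseudo-random order
#' regenerated deterministically per informed pattern.
#'
#' @param prior a [canonicalize_prior()] object.
#' @param thresholds optional named or unnamed numeric vector of per-class
#'   maximum flip counts (classes in descending-confidence order; recycled).
#' @param seed integer seed for the uninformed-bit order.
#' @return list with `next_state()` (returns a state or `NULL` when the
#'   stream is exhausted) and `emitted()` (count so far).
#' @export
start_vector_iterator <- function(prior, thresholds = NULL, seed = 1L) {
  n <- nrow(prior)
  guess <- as.integer(prior$guess)
  uninf <- which(prior$uninformed)
  n2 <- length(uninf)
  informed_probs <- sort(unique(prior$prob[prior$prob < 1 & !prior$uninformed]),
                         decreasing = TRUE)
  h <- length(informed_probs)
  # class positions ordered by increasing significance (descending node idx)
  class_pos <- lapply(informed_probs, function(p)
    rev(which(prior$prob == p & !prior$uninformed)))
  sizes <- lengths(class_pos)
  weights <- log(informed_probs / (1 - informed_probs))
  if (is.null(thresholds)) thresholds <- sizes else
    thresholds <- rep_len(thresholds, h)
  tuples <- tuple_iterator(sizes, weights, thresholds)

  cur_tuple <- NULL
  combos <- NULL        # per-class combination iterators
  cur_combos <- NULL    # current per-class combinations
  pattern_idx <- 0      # informed-pattern counter (blocks for uninformed order)
  uj <- 0               # position within the uninformed block
  emitted <- 0

  reset_combos_from <- function(c0) {
    # (re)start combination iterators for classes c0..h and pull their first
    for (c in c0:h) {
      combos[[c]] <<- combo_iterator(sizes[c], cur_tuple[c])
      cur_combos[[c]] <<- combos[[c]]$next_combo()
    }
  }
  advance_informed <- function() {
    # next Cartesian point: innermost class (h) fastest, outer classes slower
    if (is.null(cur_tuple)) {
      repeat {
        t <- tuples$next_tuple()
        if (is.null(t)) return(FALSE)
        cur_tuple <<- t
        combos <<- vector("list", h)
        cur_combos <<- vector("list", h)
        if (h == 0L) return(TRUE)
        reset_combos_from(1L)
        if (!any(vapply(cur_combos, is.null, TRUE))) return(TRUE)
      }
    }
    if (h == 0L) { cur_tuple <<- NULL; return(advance_informed()) }
    c <- h
    repeat {
      nxt <- combos[[c]]$next_combo()
      if (!is.null(nxt)) {
        cur_combos[[c]] <<- nxt
        if (c < h) reset_combos_from(c + 1L)
        return(TRUE)
      }
      if (c == 1L) { cur_tuple <<- NULL; return(advance_informed()) }
      c <- c - 1L
    }
  }
  build_state <- function() {
    v <- guess
    if (h > 0L) for (c in seq_len(h)) {
      at <- class_pos[[c]][cur_combos[[c]]]
      v[at] <- 1L - v[at]
    }
    if (n2 > 0L) {
      bits <- uninformed_order_bits(uj, n2, seed, pattern_idx)
      v[uninf] <- bits
    }
    v
  }
  list(
    next_state = function() {
      if (n2 > 0L && uj > 0 && uj < 2^n2) {
        uj <<- uj + 1
      } else {
        if (!advance_informed()) {
          if (is.null(cur_tuple) && (n2 == 0L || uj >= 2^n2)) return(NULL)
          return(NULL)
        }
        pattern_idx <<- pattern_idx + 1
        uj <<- if (n2 > 0L) 1 else 0
      }
      emitted <<- emitted + 1
      build_state()
    },
    emitted = function() emitted
  )
}
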