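# Closed-form expected-trial theory.
#
# With a uniform confidence p > 0.5 over n bits, the trial index of the
# target vector is S(n, k) + j where k is the number of mis-guessed bits and
# j the within-weight rank, so the exact expectation is
#   E(n, p) = sum_k p^(n-k) (1-p)^k [ C(n,k) S(n,k) + C(n,k)(C(n,k)+1)/2 ]
# (the inner sum over j collapsed in closed form).  The exponential envelope
# is f(alpha*)^n n^2 with
#   alpha* = 1 / (1 + sqrt(p / (1-p))),
#   beta   = (1/a)^a (1/(1-a))^(1-a),
#   f(a)   = p^(1-a) (1-p)^a beta^2,
# which is < 2 for every p > 0.5 and equals 2 at p = 0.5.

#' Exponential base of the expected-trials envelope
#'
#' @param p confidence in `[0.5, 1)`.
#' @return object of class `prior_complexity` with `p`, `alpha_star`, `beta`,
#'   `base` (`f(alpha*)`, raw double) and `base_3dp` (rounded to 3 decimals,
#'   the reporting precision).
#' @examples
#' complexity_base(0.7)$base_3dp  # 1.917
#' complexity_base(0.9)$base_3dp  # 1.600
#' @export
complexity_base <- function(p) {
  if (p < 0.5 || p >= 1) stop("p must lie in [0.5, 1)", call. = FALSE)
  a <- 1 / (1 + sqrt(p / (1 - p)))
  beta <- (1 / a)^a * (1 / (1 - a))^(1 - a)
  base <- p^(1 - a) * (1 - p)^a * beta^2
  structure(list(p = p, alpha_star = a, beta = beta, base = base,
                 base_3dp = round(base, 3)),
            class = "prior_complexity")
}

#' @export
print.prior_complexity <- function(x, ...) {
  cat(sprintf("p = %g: alpha* = %.6g, beta = %.6g, base f(alpha*) = %.3f\n",
              x$p, x$alpha_star, x$beta, x$base))
  invisible(x)
}

#' Exact expected number of trials until the target vector is examined
#'
#' @param n number of bits (>= 1).
#' @param p uniform confidence in `[0.5, 1]` (0.5 = uninformed order, 1 =
#'   the guess is certain and examined first).
#' @param log return `log(E)` instead (used for large `n`, where the terms
#'   overflow doubles and the sum is taken by log-sum-exp).
#' @return a double; exact (in double arithmetic) for moderate `n`.
#' @examples
#' expected_trials(1, 3/4)  # 5/4
#' expected_trials(2, 3/4)  # 7/4
#' @export
expected_trials <- function(n, p, log = FALSE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (p < 0.5 || p > 1) stop("p must lie in [0.5, 1]", call. = FALSE)
  k <- 0:n
  if (p == 1) {
    # all mass on k = 0, first trial; 0^0 taken as 1
    return(if (log) 0 else 1)
  }
  if (n <= 500) {
    C <- choose(n, k)
    S <- cumsum(c(0, C))[seq_len(n + 1)]
    val <- sum(p^(n - k) * (1 - p)^k * (C * S + C * (C + 1) / 2))
    return(if (log) base::log(val) else val)
  }
  # log domain: log of C*S + C(C+1)/2 via log-sum-exp over the S summands
  lC <- lchoose(n, k)
  lS <- c(-Inf, vapply(seq_len(n), function(kk)
    logsumexp(lchoose(n, 0:(kk - 1))), 0))
  lterm1 <- lC + lS
  lterm2 <- 2 * lC - base::log(2) + base::log1p(exp(-lC))  # log(C*(C+1)/2)
  linner <- pmax(lterm1, lterm2) +
    base::log1p(exp(pmin(lterm1, lterm2) - pmax(lterm1, lterm2)))
  lval <- logsumexp((n - k) * base::log(p) + k * base::log1p(-p) + linner)
  if (log) lval else exp(lval)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(x - m)))
}

#' Ratio of naive enumeration to the guided-search envelope
#'
#' `2^n / (base^n * n^2)`, computed in log domain (no overflow even for very
#' large `n`).  The default base is the printed 3-decimal value 1.917 for
#' p = 0.7, the scale on which the naive comparison is usually quoted.
#'
#' @param n network size.
#' @param base exponential base of the envelope.
#' @return a double.
#' @examples
#' naive_ratio(100)   # ~0.00693: the envelope only wins for larger n
#' naive_ratio(1000)  # ~2.558e12
#' @export
naive_ratio <- function(n, base = 1.917) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  exp(n * base::log(2) - n * base::log(base) - 2 * base::log(n))
}

#' Expected-trials envelope f(alpha*)^n * n^2
#'
#' The asymptotic envelope with its unspecified constant factor fixed at 1;
#' an upper-bound curve for comparison plots, not an exact expectation.
#'
#' @inheritParams expected_trials
#' @param log return the natural log of the envelope.
#' @export
theoretical_trial_bound <- function(n, p, log = FALSE) {
  if (p <= 0.5 || p >= 1) stop("p must lie in (0.5, 1)", call. = FALSE)
  lb <- n * base::log(complexity_base(p)$base) + 2 * base::log(n)
  if (log) lb else exp(lb)
}

#' Envelope for a semi-informed prior
#'
#' With confidence p on `n1` bits and no information on the remaining `n2`
#' bits (enumerated innermost in random order), the trial envelope is
#' `f(alpha*)^n1 * 2^n2 * n1^2` — still below `2^(n1+n2) * n1^2` whenever
#' p > 0.5.
#'
#' @param n1 informed bits (>= 1), `n2` uninformed bits (>= 0).
#' @inheritParams theoretical_trial_bound
#' @export
semi_informed_bound <- function(n1, n2, p, log = FALSE) {
  if (n1 < 1 || n2 < 0) stop("need n1 >= 1 and n2 >= 0", call. = FALSE)
  lb <- theoretical_trial_bound(n1, p, log = TRUE) + n2 * base::log(2)
  if (log) lb else exp(lb)
}
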