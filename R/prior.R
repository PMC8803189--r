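# Per-node a priori information: a guess bit and a confidence.

#' Canonicalize per-node a priori information
#'
#' Each node carries a guess bit and the probability that the node takes
#' that value in some state of the target attractor.  Canonicalization
#' exchanges the roles of 0 and 1 wherever the probability is below 0.5, so
#' that afterwards every confidence is at least 0.5: guessing 1 with
#' probability 0.3 is the same information as guessing 0 with probability
#' 0.7.  Nodes with equal confidence form a class; classes are ordered by
#' descending confidence.  Confidence 1 marks bits that are never flipped;
#' confidence 0.5 marks uninformed bits.
#'
#' @param guess integer 0/1 vector (or named vector matching `nodes`).
#' @param prob probabilities in (0, 1], recycled to the number of nodes.
#' @param nodes optional node names.
#' @return an object of class `bn_prior`: data frame columns `node`, `guess`,
#'   `prob` (canonical, all >= 0.5), `class_id` (1 = highest confidence) and
#'   `uninformed`.
#' @examples
#' canonicalize_prior(c(1, 0, 0), c(0.3, 0.75, 0.5))
#' @export
canonicalize_prior <- function(guess, prob, nodes = NULL) {
  n <- length(guess)
  prob <- rep_len(prob, n)
  if (any(prob <= 0 | prob > 1))
    stop("prior probabilities must lie in (0, 1]", call. = FALSE)
  guess <- as.integer(guess)
  if (any(guess != 0L & guess != 1L))
    stop("guess bits must be 0 or 1", call. = FALSE)
  flip <- prob < 0.5
  guess[flip] <- 1L - guess[flip]
  prob[flip] <- 1 - prob[flip]
  if (is.null(nodes)) nodes <- names(guess)
  auto_names <- is.null(nodes)
  if (auto_names) nodes <- paste0("x", seq_len(n))
  lv <- sort(unique(prob), decreasing = TRUE)
  out <- data.frame(node = nodes, guess = guess, prob = prob,
                    class_id = match(prob, lv),
                    uninformed = prob == 0.5,
                    stringsAsFactors = FALSE)
  class(out) <- c("bn_prior", "data.frame")
  attr(out, "auto_names") <- auto_names
  out
}

#' @export
print.bn_prior <- function(x, ...) {
  cat(sprintf("A priori information for %d nodes (%d confidence class%s)\n",
              nrow(x), length(unique(x$class_id)),
              if (length(unique(x$class_id)) == 1L) "" else "es"))
  for (p in sort(unique(x$prob), decreasing = TRUE)) {
    tag <- if (p == 1) "fixed" else if (p == 0.5) "uninformed" else "informed"
    cat(sprintf("  p = %-5g %4d node(s)  [%s]\n", p, sum(x$prob == p), tag))
  }
  invisible(x)
}

#' Read a prior file
#'
#' Tab-separated file with header `node<TAB>guess<TAB>prob`; `guess` in
#' {0, 1}, `prob` in (0, 1].  Nodes of the network absent from the file
#' default to uninformed (guess 0, prob 0.5) with a message.
#'
#' @param file path to the TSV file.
#' @param net optional [boolean_network()]; when given, the prior is aligned
#'   to the network's node order and missing nodes are filled in.
#' @return a [canonicalize_prior()] object.
#' @export
read_prior <- function(file, net = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("node", "guess", "prob")
  if (!all(need %in% names(tab)))
    stop("prior file needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$node))
    stop("duplicate node in prior file: ",
         paste(unique(tab$node[duplicated(tab$node)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(net)) {
    unknown <- setdiff(tab$node, net$nodes)
    if (length(unknown) > 0L)
      stop("prior file names node(s) not in the network: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    missing <- setdiff(net$nodes, tab$node)
    if (length(missing) > 0L) {
      message(length(missing), " node(s) absent from prior file; ",
              "defaulting to uninformed (guess 0, prob 0.5)")
      tab <- rbind(tab, data.frame(node = missing, guess = 0L, prob = 0.5,
                                   stringsAsFactors = FALSE))
    }
    tab <- tab[match(net$nodes, tab$node), ]
  }
  canonicalize_prior(tab$guess, tab$prob, nodes = tab$node)
}

#' Build a uniform prior around a guess state
#'
#' Convenience wrapper: every node gets the same confidence.
#'
#' @param guess 0/1 vector.
#' @param prob single confidence in (0, 1].
#' @param nodes optional names.
#' @export
uniform_prior <- function(guess, prob, nodes = NULL)
  canonicalize_prior(guess, rep(prob, length(guess)), nodes = nodes)
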