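# Synchronous Boolean networks and the "targets, factors" text dialect.

#' Construct a synchronous Boolean network
#'
#' A network is an ordered set of named nodes, each carrying one Boolean
#' update expression over other nodes (its input set).  All nodes update
#' simultaneously from the same current global state.
#'
#' @param nodes character vector of unique node names (declaration order is
#'   the state-vector order).
#' @param rules list of expression trees, one per node.
#' @return an object of class `boolean_network` with fields `nodes`, `rules`,
#'   `inputs` (per-node input sets, order of first appearance) and
#'   `indegrees`.
#' @export
boolean_network <- function(nodes, rules) {
  if (length(nodes) < 1L) stop("a network needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes))
    stop("duplicate node name: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "), call. = FALSE)
  if (length(rules) != length(nodes))
    stop("need exactly one update rule per node", call. = FALSE)
  inputs <- lapply(rules, expression_variables)
  undeclared <- setdiff(unique(unlist(inputs)), nodes)
  if (length(undeclared) > 0L)
    stop("undeclared node(s) referenced in rules: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  names(rules) <- nodes
  names(inputs) <- nodes
  structure(
    list(nodes = nodes, rules = rules, inputs = inputs,
         indegrees = lengths(inputs)),
    class = "boolean_network")
}

#' Number of nodes of a Boolean network
#' @param net a `boolean_network`.
#' @export
network_size <- function(net) length(net$nodes)

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Synchronous Boolean network: %d nodes, indegree %s\n",
              network_size(x),
              if (length(unique(x$indegrees)) == 1L)
                as.character(x$indegrees[1L])
              else sprintf("%d-%d", min(x$indegrees), max(x$indegrees))))
  show <- min(length(x$nodes), 10L)
  for (i in seq_len(show))
    cat(sprintf("  %s, %s\n", x$nodes[i], deparse_expression(x$rules[[i]])))
  if (show < length(x$nodes))
    cat(sprintf("  ... (%d more)\n", length(x$nodes) - show))
  invisible(x)
}

#' Parse a network from the "targets, factors" dialect
#'
#' The dialect is the BoolNet file format restricted to plain rules: a header
#' line `targets, factors`, then one line per node of the form
#' `name, expression` with operators `!`, `&`, `|`, parentheses and the
#' constants `0`/`1`.  `#` starts a comment; blank lines are ignored; node
#' names are case-sensitive and match `[A-Za-z_][A-Za-z0-9_./-]*`.
#' Probabilistic rules and BoolNet extended functions are rejected.
#'
#' @param text the network source as a single string or character vector of
#'   lines; mutually exclusive with `file`.
#' @param file path to a network file.
#' @return a [boolean_network()].
#' @examples
#' net <- parse_network("targets, factors\nx1, x3\nx2, x1 & ! x3\nx3, x1 & ! x2")
#' net$indegrees
#' @export
parse_network <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 2L)
    stop("network source needs a header line and at least one rule line",
         call. = FALSE)
  header <- trimws(lines[keep[1L]])
  if (!grepl("^targets\\s*,\\s*factors$", header, ignore.case = TRUE))
    stop(sprintf("line %d: expected header 'targets, factors', found '%s'",
                 keep[1L], header), call. = FALSE)
  nodes <- character(0)
  rules <- list()
  for (ln in keep[-1L]) {
    raw <- trimws(lines[ln])
    comma <- regexpr(",", raw, fixed = TRUE)
    if (comma < 0L)
      stop(sprintf("line %d: expected 'name, expression', found '%s'", ln, raw),
           call. = FALSE)
    name <- trimws(substr(raw, 1L, comma - 1L))
    body <- trimws(substr(raw, comma + 1L, nchar(raw)))
    if (grepl(",", body, fixed = TRUE))
      stop(sprintf(paste0("line %d: multiple comma-separated factors ",
                          "(probabilistic BoolNet rules are not supported)"), ln),
           call. = FALSE)
    if (!grepl(paste0("^", .bn_name_re, "$"), name))
      stop(sprintf("line %d: invalid node name '%s'", ln, name), call. = FALSE)
    if (name %in% nodes)
      stop(sprintf("line %d: duplicate node name '%s'", ln, name), call. = FALSE)
    rule <- tryCatch(parse_expression(body), error = function(e)
      stop(sprintf("line %d: %s", ln, conditionMessage(e)), call. = FALSE))
    nodes <- c(nodes, name)
    rules <- c(rules, list(rule))
  }
  boolean_network(nodes, rules)
}

#' Serialize a network to the "targets, factors" dialect
#'
#' `parse_network(serialize_network(net))` reproduces a network with
#' identical per-node truth tables.
#'
#' @param net a `boolean_network`.
#' @param file optional path; when given the text is written there.
#' @return the dialect text, invisibly when `file` is given.
#' @export
serialize_network <- function(net, file = NULL) {
  out <- c("targets, factors",
           vapply(seq_along(net$nodes), function(i)
             paste0(net$nodes[i], ", ", deparse_expression(net$rules[[i]])), ""))
  text <- paste(out, collapse = "\n")
  if (!is.null(file)) { writeLines(text, file); return(invisible(text)) }
  text
}

# Compile the network for fast stepping: nodes with indegree <= table_limit
# get a truth-table lookup (input index vector + 2^k table, first input most
# significant); larger rules fall back to expression evaluation, keeping the
# per-step cost proportional to total expression size rather than 2^k.
compile_network <- function(net, table_limit = 12L) {
  n <- network_size(net)
  idx <- lapply(net$inputs, function(inp) match(inp, net$nodes))
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    k <- net$indegrees[i]
    if (k > table_limit) next
    tab <- integer(2^k)
    if (k == 0L) {
      tab[1L] <- evaluate_expression(net$rules[[i]], integer(0))
    } else {
      for (r in seq_len(2^k)) {
        a <- bitwAnd(bitwShiftR(r - 1L, (k - 1L):0L), 1L)
        names(a) <- net$inputs[[i]]
        tab[r] <- evaluate_expression(net$rules[[i]], a)
      }
    }
    tables[[i]] <- tab
  }
  weights <- lapply(net$indegrees, function(k)
    if (k >= 1L) 2^((k - 1L):0L) else numeric(0))
  list(n = n, idx = idx, tables = tables, weights = weights,
       nodes = net$nodes, rules = net$rules)
}

# One synchronous update on a compiled network.
step_compiled <- function(cnet, state) {
  out <- integer(cnet$n)
  for (i in seq_len(cnet$n)) {
    tab <- cnet$tables[[i]]
    if (!is.null(tab)) {
      k <- length(cnet$idx[[i]])
      r <- if (k == 0L) 1L else sum(state[cnet$idx[[i]]] * cnet$weights[[i]]) + 1L
      out[i] <- tab[r]
    } else {
      a <- state
      names(a) <- cnet$nodes
      out[i] <- evaluate_expression(cnet$rules[[i]], a)
    }
  }
  out
}

#' Synchronous update of a global state
#'
#' All nodes are updated simultaneously from the same input state.
#'
#' @param net a `boolean_network`.
#' @param state integer vector of 0/1, one value per node in node order.
#' @return the successor state (integer 0/1 vector).
#' @export
step_network <- function(net, state) {
  state <- check_state(state, network_size(net))
  step_compiled(compile_network(net), state)
}

# Truth table of node i over its declared inputs (first input most
# significant); used for round-trip equivalence checks.
node_truth_table <- function(net, i) {
  k <- net$indegrees[i]
  if (k == 0L)
    return(evaluate_expression(net$rules[[i]], integer(0)))
  vapply(seq_len(2^k), function(r) {
    a <- bitwAnd(bitwShiftR(r - 1L, (k - 1L):0L), 1L)
    names(a) <- net$inputs[[i]]
    evaluate_expression(net$rules[[i]], a)
  }, integer(1))
}

# Semantic equality of two networks: same node order and identical per-node
# truth tables over identically ordered input sets (input order may differ
# between equivalent expressions, so tables are compared over the union).
networks_equivalent <- function(a, b) {
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  for (i in seq_along(a$nodes)) {
    inp <- union(a$inputs[[i]], b$inputs[[i]])
    k <- length(inp)
    if (k > 16L) stop("equivalence check limited to 16 inputs", call. = FALSE)
    rows <- if (k == 0L) matrix(integer(0), 1L, 0L) else
      as.matrix(expand.grid(rep(list(0:1), k)))
    for (r in seq_len(nrow(rows))) {
      asg <- as.integer(rows[r, ])
      names(asg) <- inp
      if (evaluate_expression(a$rules[[i]], asg) !=
          evaluate_expression(b$rules[[i]], asg)) return(FALSE)
    }
  }
  TRUE
}
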