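# Boolean update expressions.
#
# An expression is a nested list with a `type` field:
#   const: list(type = "const", value = 0L or 1L)
#   var:   list(type = "var",   name = <node name>)
#   not:   list(type = "not",   arg = <expression>)       (unary)
#   and:   list(type = "and",   args = list(...))          (n-ary, >= 2)
#   or:    list(type = "or",    args = list(...))          (n-ary, >= 2)
#
# Node names match [A-Za-z_][A-Za-z0-9_./-]* (biological models use slashes
# and dots), which is why rules are parsed by hand rather than through R's
# own parser.

bn_const <- function(value) list(type = "const", value = as.integer(value))
bn_var   <- function(name)  list(type = "var", name = name)
bn_not   <- function(arg)   list(type = "not", arg = arg)
bn_and   <- function(args)  if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
bn_or    <- function(args)  if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)

.bn_name_re <- "[A-Za-z_][A-Za-z0-9_./-]*"

# Tokenize one rule expression.  Returns a data.frame(kind, text).
tokenize_expression <- function(text) {
  kinds <- character(0)
  texts <- character(0)
  i <- 1L
  nch <- nchar(text)
  while (i <= nch) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      kinds <- c(kinds, ch); texts <- c(texts, ch); i <- i + 1L; next
    }
    if (ch %in% c("0", "1")) {
      # a digit starting a token is a constant; names cannot start with digits
      kinds <- c(kinds, "const"); texts <- c(texts, ch); i <- i + 1L; next
    }
    m <- regmatches(substr(text, i, nch),
                    regexpr(paste0("^", .bn_name_re), substr(text, i, nch)))
    if (length(m) == 1L && nzchar(m)) {
      kinds <- c(kinds, "name"); texts <- c(texts, m); i <- i + nchar(m); next
    }
    stop(sprintf("unexpected character '%s' at position %d in expression: %s",
                 ch, i, text), call. = FALSE)
  }
  data.frame(kind = kinds, text = texts, stringsAsFactors = FALSE)
}

# Recursive-descent parser: expr := term ('|' term)* ; term := factor ('&'
# factor)* ; factor := '!' factor | '(' expr ')' | name | 0 | 1.
parse_expression <- function(text) {
  if (grepl("\\b(all|any|maj|sumgt|sumlt)\\s*\\(", text))
    stop("BoolNet extended functions (all(), any(), ...) are not supported; ",
         "only !, &, |, parentheses and the constants 0/1 are accepted",
         call. = FALSE)
  toks <- tokenize_expression(text)
  pos <- 1L
  peek <- function() if (pos > nrow(toks)) NULL else toks[pos, ]
  advance <- function() { t <- toks[pos, ]; pos <<- pos + 1L; t }
  expect <- function(kind) {
    t <- peek()
    if (is.null(t) || t$kind != kind)
      stop(sprintf("expected '%s' but found '%s' in expression: %s", kind,
                   if (is.null(t)) "end of input" else t$text, text),
           call. = FALSE)
    advance()
  }
  p_factor <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of expression: ", text, call. = FALSE)
    if (t$kind == "!") { advance(); return(bn_not(p_factor())) }
    if (t$kind == "(") {
      advance(); e <- p_expr(); expect(")"); return(e)
    }
    if (t$kind == "const") { advance(); return(bn_const(t$text == "1")) }
    if (t$kind == "name") { advance(); return(bn_var(t$text)) }
    stop(sprintf("unexpected token '%s' in expression: %s", t$text, text),
         call. = FALSE)
  }
  p_term <- function() {
    args <- list(p_factor())
    while (!is.null(t <- peek()) && t$kind == "&") { advance(); args <- c(args, list(p_factor())) }
    bn_and(args)
  }
  p_expr <- function() {
    args <- list(p_term())
    while (!is.null(t <- peek()) && t$kind == "|") { advance(); args <- c(args, list(p_term())) }
    bn_or(args)
  }
  e <- p_expr()
  if (!is.null(t <- peek()))
    stop(sprintf("trailing input '%s' in expression: %s", t$text, text),
         call. = FALSE)
  e
}

#' Evaluate a Boolean expression on a full assignment
#'
#' @param expr an expression tree as produced by the network parser.
#' @param assignment named integer vector of 0/1 node values covering every
#'   variable referenced by `expr`.
#' @return 0L or 1L.
#' @export
evaluate_expression <- function(expr, assignment) {
  switch(expr$type,
    const = expr$value,
    var = {
      i <- match(expr$name, names(assignment))
      if (is.na(i) || is.na(assignment[[i]]))
        stop("unbound variable: ", expr$name, call. = FALSE)
      as.integer(assignment[[i]])
    },
    not = 1L - evaluate_expression(expr$arg, assignment),
    and = {
      for (a in expr$args) if (evaluate_expression(a, assignment) == 0L) return(0L)
      1L
    },
    or = {
      for (a in expr$args) if (evaluate_expression(a, assignment) == 1L) return(1L)
      0L
    },
    stop("unknown expression type: ", expr$type, call. = FALSE)
  )
}

# Variables referenced by an expression, in order of first appearance.
expression_variables <- function(expr) {
  switch(expr$type,
    const = character(0),
    var = expr$name,
    not = expression_variables(expr$arg),
    and = ,
    or = unique(unlist(lapply(expr$args, expression_variables))),
    stop("unknown expression type: ", expr$type, call. = FALSE)
  )
}

# Serialize with minimal parentheses (| lowest, & middle, ! highest).
deparse_expression <- function(expr, parent = "or") {
  prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  s <- switch(expr$type,
    const = as.character(expr$value),
    var = expr$name,
    not = paste0("!", deparse_expression(expr$arg, "not")),
    and = paste(vapply(expr$args, deparse_expression, "", parent = "and"),
                collapse = " & "),
    or = paste(vapply(expr$args, deparse_expression, "", parent = "or"),
               collapse = " | ")
  )
  if (prec[[expr$type]] < prec[[parent]]) paste0("(", s, ")") else s
}
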