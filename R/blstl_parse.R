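#' @title PBLSTL parsing
#'
#' @description Recursive-descent parser for Probabilistic Bounded Linear
#' Spatial Temporal Logic specifications. A specification is one or more
#' statements of the form `P >= 0.9 [ formula ]` where the formula combines
#' bounded temporal operators (`F [a, b]`, `G [a, b]`, binary `U [a, b]`,
#' `X [k]`), Boolean connectives (`~`, `^`, `V`, `=>`, `<=>`), comparisons
#' of numeric expressions, numeric state variable references `{name}`, the
#' difference operator `d(...)`, arithmetic functions, and statistical
#' functions over the dynamic collections `regions` and `clusters`
#' (optionally restricted with `filter(collection, constraint)`).
#' The concrete grammar ships with the package as
#' `system.file("extdata", "pblstl_grammar.ebnf", package = "stmc")`.
#'
#' @name blstl-parsing
NULL

blstl_unary_fns <- c("abs", "ceil", "floor", "round", "sign", "sqrt", "trunc")
blstl_binary_fns <- c("add", "subtract", "multiply", "divide", "power",
                      "min", "max")
blstl_stat_fns <- c("count", "mean", "median", "mode", "min", "max", "sum",
                    "stdev", "percentile", "covariance")

blstl_syntax_error <- function(msg, tok = NULL, expected = NULL) {
  loc <- if (!is.null(tok)) sprintf(" at line %d, column %d (near '%s')",
                                    tok$line, tok$col, tok$text) else ""
  exp <- if (!is.null(expected))
    sprintf("; expected one of: %s", paste(expected, collapse = ", ")) else ""
  stop(structure(class = c("blstl_syntax_error", "error", "condition"),
                 list(message = paste0("PBLSTL syntax error", loc, ": ",
                                       msg, exp),
                      call = NULL)))
}

blstl_semantic_error <- function(msg) {
  stop(structure(class = c("blstl_semantic_error", "error", "condition"),
                 list(message = paste0("PBLSTL semantic error: ", msg),
                      call = NULL)))
}

tokenize_pblstl <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) lines <- ""
  toks <- list()
  patterns <- list(
    c("VARREF", "^\\{[^}]+\\}"),
    c("NUMBER", "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?"),
    c("IDENT", "^[A-Za-z_][A-Za-z0-9_]*"),
    c("OP", "^(<=>|=>|>=|<=|[][<>=(),^~-])"))
  for (ln in seq_along(lines)) {
    s <- sub("#.*$", "", lines[ln])
    col <- 1L
    while (nchar(s) > 0) {
      ws <- regmatches(s, regexpr("^[[:space:]]+", s))
      if (length(ws) && nchar(ws)) {
        col <- col + nchar(ws)
        s <- substring(s, nchar(ws) + 1)
        next
      }
      if (!nchar(s)) break
      matched <- FALSE
      for (p in patterns) {
        mm <- regmatches(s, regexpr(p[2], s))
        if (length(mm) && nchar(mm)) {
          toks[[length(toks) + 1L]] <-
            list(type = p[1], text = mm, line = ln, col = col)
          col <- col + nchar(mm)
          s <- substring(s, nchar(mm) + 1)
          matched <- TRUE
          break
        }
      }
      if (!matched)
        blstl_syntax_error(sprintf("unexpected character '%s'",
                                   substring(s, 1, 1)),
                           list(line = ln, col = col,
                                text = substring(s, 1, 1)))
    }
  }
  toks
}

new_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env
}

p_peek <- function(p, ahead = 0L) {
  i <- p$pos + ahead
  if (i > length(p$tokens)) list(type = "EOF", text = "<end of input>",
                                 line = NA_integer_, col = NA_integer_)
  else p$tokens[[i]]
}

p_advance <- function(p) {
  tok <- p_peek(p)
  p$pos <- p$pos + 1L
  tok
}

p_expect <- function(p, text = NULL, type = NULL) {
  tok <- p_peek(p)
  ok <- (!is.null(text) && identical(tok$text, text)) ||
    (!is.null(type) && identical(tok$type, type))
  if (!ok)
    blstl_syntax_error(sprintf("found '%s'", tok$text), tok,
                       expected = c(text, type))
  p_advance(p)
}

p_accept <- function(p, text) {
  if (identical(p_peek(p)$text, text)) { p_advance(p); TRUE } else FALSE
}

#' Parse a PBLSTL specification
#'
#' @param text Specification text: one or more `P comparator theta [ ... ]`
#'   statements; `#` starts a line comment.
#' @return List of `pblstl_statement` objects, each with fields
#'   `comparator` (one of `<`, `<=`, `>`, `>=`), `theta` (strictly inside
#'   (0, 1)) and `formula` (the BLSTL syntax tree).
#' @export
parse_pblstl <- function(text) {
  p <- new_parser(tokenize_pblstl(text))
  statements <- list()
  while (p_peek(p)$type != "EOF") {
    statements[[length(statements) + 1L]] <- parse_statement(p)
  }
  if (!length(statements))
    blstl_syntax_error("specification contains no statements",
                       p_peek(p))
  statements
}

#' Parse a PBLSTL specification file
#'
#' @param path UTF-8 text file with one or more PBLSTL statements.
#' @return As [parse_pblstl()].
#' @export
parse_pblstl_file <- function(path) {
  parse_pblstl(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                     collapse = "\n"))
}

parse_statement <- function(p) {
  tok <- p_peek(p)
  if (!(tok$type == "IDENT" && tok$text == "P"))
    blstl_syntax_error(sprintf("found '%s'", tok$text), tok, expected = "P")
  p_advance(p)
  cmp_tok <- p_peek(p)
  if (!cmp_tok$text %in% c("<", "<=", ">", ">="))
    blstl_syntax_error(sprintf("found '%s'", cmp_tok$text), cmp_tok,
                       expected = c("<", "<=", ">", ">="))
  p_advance(p)
  theta_tok <- p_expect(p, type = "NUMBER")
  theta <- as.numeric(theta_tok$text)
  if (theta <= 0 || theta >= 1)
    blstl_semantic_error(sprintf(
      "probability threshold %s lies outside the open interval (0, 1)",
      theta_tok$text))
  p_expect(p, "[")
  formula <- parse_formula(p)
  p_expect(p, "]")
  structure(list(comparator = cmp_tok$text, theta = theta,
                 formula = formula),
            class = "pblstl_statement")
}

#' @export
print.pblstl_statement <- function(x, ...) {
  cat(sprintf("PBLSTL statement: P %s %s [ %s ]\n",
              x$comparator, format(x$theta), deparse_blstl(x$formula)))
  invisible(x)
}

parse_formula <- function(p) parse_iff(p)

parse_iff <- function(p) {
  left <- parse_implies(p)
  while (p_accept(p, "<=>"))
    left <- list(kind = "iff", left = left, right = parse_implies(p))
  left
}

parse_implies <- function(p) {
  left <- parse_or(p)
  if (p_accept(p, "=>"))
    return(list(kind = "implies", left = left, right = parse_implies(p)))
  left
}

parse_or <- function(p) {
  left <- parse_and(p)
  while (p_peek(p)$type == "IDENT" && p_peek(p)$text == "V") {
    p_advance(p)
    left <- list(kind = "or", left = left, right = parse_and(p))
  }
  left
}

parse_and <- function(p) {
  left <- parse_until(p)
  while (p_accept(p, "^"))
    left <- list(kind = "and", left = left, right = parse_until(p))
  left
}

parse_until <- function(p) {
  left <- parse_unary_formula(p)
  while (p_peek(p)$type == "IDENT" && p_peek(p)$text == "U") {
    p_advance(p)
    b <- parse_bounds(p)
    right <- parse_unary_formula(p)
    left <- list(kind = "until", a = b[1], b = b[2],
                 left = left, right = right)
  }
  left
}

parse_bounds <- function(p) {
  p_expect(p, "[")
  a_tok <- p_expect(p, type = "NUMBER")
  p_expect(p, ",")
  b_tok <- p_expect(p, type = "NUMBER")
  p_expect(p, "]")
  a <- as.numeric(a_tok$text); b <- as.numeric(b_tok$text)
  if (a > b)
    blstl_semantic_error(sprintf("temporal bounds [%s, %s] must satisfy a <= b",
                                 a_tok$text, b_tok$text))
  c(a, b)
}

parse_unary_formula <- function(p) {
  tok <- p_peek(p)
  if (tok$text == "~") {
    p_advance(p)
    return(list(kind = "not", child = parse_unary_formula(p)))
  }
  if (tok$type == "IDENT" && tok$text %in% c("F", "G") &&
      p_peek(p, 1L)$text == "[") {
    p_advance(p)
    b <- parse_bounds(p)
    return(list(kind = tok$text, a = b[1], b = b[2],
                child = parse_unary_formula(p)))
  }
  if (tok$type == "IDENT" && tok$text == "X" && p_peek(p, 1L)$text == "[") {
    p_advance(p)
    p_expect(p, "[")
    k_tok <- p_expect(p, type = "NUMBER")
    p_expect(p, "]")
    k <- as.numeric(k_tok$text)
    if (k != floor(k) || k < 1)
      blstl_semantic_error("X[k] requires a positive integer k")
    return(list(kind = "X", k = as.integer(k),
                child = parse_unary_formula(p)))
  }
  parse_atom(p)
}

parse_atom <- function(p) {
  # '(' may open either a parenthesised formula or a grouped numeric
  # expression; resolve by backtracking.
  if (p_peek(p)$text == "(") {
    save <- p$pos
    res <- tryCatch({
      p_advance(p)
      f <- parse_formula(p)
      p_expect(p, ")")
      # a comparison operator after the closing paren means the inner text
      # was a numeric group after all; force backtrack
      if (p_peek(p)$text %in% c("<", "<=", "=", ">=", ">")) stop("numeric")
      f
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    p$pos <- save
  }
  parse_comparison(p)
}

parse_comparison <- function(p) {
  lhs <- parse_numeric(p)
  op_tok <- p_peek(p)
  if (!op_tok$text %in% c("<", "<=", "=", ">=", ">"))
    blstl_syntax_error(sprintf("found '%s'", op_tok$text), op_tok,
                       expected = c("<", "<=", "=", ">=", ">"))
  p_advance(p)
  rhs <- parse_numeric(p)
  list(kind = "cmp", op = op_tok$text, lhs = lhs, rhs = rhs)
}

is_collection_start <- function(p) {
  tok <- p_peek(p)
  tok$type == "IDENT" && tok$text %in% c("regions", "clusters", "filter")
}

parse_numeric <- function(p) {
  tok <- p_peek(p)
  if (tok$text == "-") {
    p_advance(p)
    return(list(kind = "unary", fn = "negate", child = parse_numeric(p)))
  }
  if (tok$type == "NUMBER") {
    p_advance(p)
    return(list(kind = "num", value = as.numeric(tok$text)))
  }
  if (tok$type == "VARREF") {
    p_advance(p)
    return(list(kind = "var",
                name = substring(tok$text, 2, nchar(tok$text) - 1)))
  }
  if (tok$text == "(") {
    p_advance(p)
    e <- parse_numeric(p)
    p_expect(p, ")")
    return(e)
  }
  if (tok$type == "IDENT") {
    name <- tok$text
    if (name == "d") {
      p_advance(p); p_expect(p, "(")
      child <- parse_numeric(p)
      p_expect(p, ")")
      return(list(kind = "diff", child = child))
    }
    if (name %in% c(blstl_unary_fns, blstl_binary_fns, blstl_stat_fns)) {
      p_advance(p)
      p_expect(p, "(")
      if (name %in% blstl_stat_fns && is_collection_start(p)) {
        node <- parse_statistic_call(p, name)
        p_expect(p, ")")
        return(node)
      }
      if (name %in% blstl_unary_fns) {
        child <- parse_numeric(p)
        p_expect(p, ")")
        return(list(kind = "unary", fn = name, child = child))
      }
      if (name %in% blstl_binary_fns) {
        left <- parse_numeric(p)
        p_expect(p, ",")
        right <- parse_numeric(p)
        p_expect(p, ")")
        return(list(kind = "binary", fn = name, left = left, right = right))
      }
      blstl_syntax_error(
        sprintf("statistical function '%s' requires a collection argument",
                name), tok, expected = c("regions", "clusters", "filter"))
    }
  }
  blstl_syntax_error(sprintf("found '%s'", tok$text), tok,
                     expected = c("number", "{variable}", "function call",
                                  "(", "-"))
}

parse_statistic_call <- function(p, fn) {
  coll <- parse_collection(p)
  if (fn == "count")
    return(list(kind = "stat", fn = "count", collection = coll))
  p_expect(p, ",")
  measure <- parse_measure_name(p)
  if (fn == "percentile") {
    p_expect(p, ",")
    q_tok <- p_expect(p, type = "NUMBER")
    q <- as.numeric(q_tok$text)
    if (q < 0 || q > 100)
      blstl_semantic_error(sprintf("percentile %s outside [0, 100]",
                                   q_tok$text))
    return(list(kind = "stat", fn = "percentile", collection = coll,
                measure = measure, q = q))
  }
  if (fn == "covariance") {
    p_expect(p, ",")
    coll2 <- parse_collection(p)
    p_expect(p, ",")
    measure2 <- parse_measure_name(p)
    return(list(kind = "stat", fn = "covariance", collection = coll,
                measure = measure, collection2 = coll2, measure2 = measure2))
  }
  list(kind = "stat", fn = fn, collection = coll, measure = measure)
}

parse_measure_name <- function(p) {
  tok <- p_expect(p, type = "IDENT")
  if (!tok$text %in% spatial_measure_names())
    blstl_semantic_error(sprintf(
      "'%s' is not a spatial measure (valid: %s)",
      tok$text, paste(spatial_measure_names(), collapse = ", ")))
  tok$text
}

parse_collection <- function(p) {
  tok <- p_peek(p)
  if (tok$text %in% c("regions", "clusters")) {
    p_advance(p)
    return(list(kind = "coll", which = tok$text, filter = NULL))
  }
  if (tok$text == "filter") {
    p_advance(p)
    p_expect(p, "(")
    inner <- parse_collection(p)
    p_expect(p, ",")
    constraint <- parse_constraint(p)
    p_expect(p, ")")
    return(list(kind = "coll", which = inner$which,
                filter = combine_filters(inner$filter, constraint)))
  }
  blstl_syntax_error(sprintf("found '%s'", tok$text), tok,
                     expected = c("regions", "clusters", "filter"))
}

combine_filters <- function(existing, new) {
  if (is.null(existing)) new
  else list(kind = "and", left = existing, right = new)
}

# Filter constraints are Boolean combinations of measure-vs-numeric
# comparisons; numeric state variables and statistics are not allowed
# inside them.
parse_constraint <- function(p) parse_constraint_iff(p)

parse_constraint_iff <- function(p) {
  left <- parse_constraint_implies(p)
  while (p_accept(p, "<=>"))
    left <- list(kind = "iff", left = left, right = parse_constraint_implies(p))
  left
}

parse_constraint_implies <- function(p) {
  left <- parse_constraint_or(p)
  if (p_accept(p, "=>"))
    return(list(kind = "implies", left = left,
                right = parse_constraint_implies(p)))
  left
}

parse_constraint_or <- function(p) {
  left <- parse_constraint_and(p)
  while (p_peek(p)$type == "IDENT" && p_peek(p)$text == "V") {
    p_advance(p)
    left <- list(kind = "or", left = left, right = parse_constraint_and(p))
  }
  left
}

parse_constraint_and <- function(p) {
  left <- parse_constraint_unary(p)
  while (p_accept(p, "^"))
    left <- list(kind = "and", left = left, right = parse_constraint_unary(p))
  left
}

parse_constraint_unary <- function(p) {
  tok <- p_peek(p)
  if (tok$text == "~") {
    p_advance(p)
    return(list(kind = "not", child = parse_constraint_unary(p)))
  }
  if (tok$text == "(") {
    p_advance(p)
    inner <- parse_constraint(p)
    p_expect(p, ")")
    return(inner)
  }
  if (tok$type == "VARREF")
    blstl_semantic_error(paste0(
      "numeric state variable '", tok$text, "' referenced inside a filter ",
      "constraint; constraints range over spatial measures only"))
  measure <- parse_measure_name(p)
  op_tok <- p_peek(p)
  if (!op_tok$text %in% c("<", "<=", "=", ">=", ">"))
    blstl_syntax_error(sprintf("found '%s'", op_tok$text), op_tok,
                       expected = c("<", "<=", "=", ">=", ">"))
  p_advance(p)
  rhs <- parse_constraint_value(p)
  list(kind = "mcmp", op = op_tok$text, measure = measure, rhs = rhs)
}

parse_constraint_value <- function(p) {
  node <- parse_numeric(p)
  check_constraint_value <- function(n) {
    if (n$kind %in% c("var", "stat", "diff"))
      blstl_semantic_error(paste0(
        "filter constraints may compare spatial measures against constant ",
        "numeric expressions only"))
    for (f in c("child", "left", "right"))
      if (!is.null(n[[f]]) && is.list(n[[f]]) && !is.null(n[[f]]$kind))
        check_constraint_value(n[[f]])
  }
  check_constraint_value(node)
  node
}

# Compact textual rendering of a formula tree (used by print methods and
# diagnostics).
deparse_blstl <- function(n) {
  switch(n$kind,
    num = format(n$value),
    var = paste0("{", n$name, "}"),
    diff = paste0("d(", deparse_blstl(n$child), ")"),
    unary = if (n$fn == "negate") paste0("-", deparse_blstl(n$child))
            else paste0(n$fn, "(", deparse_blstl(n$child), ")"),
    binary = paste0(n$fn, "(", deparse_blstl(n$left), ", ",
                    deparse_blstl(n$right), ")"),
    stat = {
      parts <- deparse_collection(n$collection)
      if (!is.null(n$measure)) parts <- c(parts, n$measure)
      if (!is.null(n$q)) parts <- c(parts, format(n$q))
      if (!is.null(n$collection2))
        parts <- c(parts, deparse_collection(n$collection2), n$measure2)
      paste0(n$fn, "(", paste(parts, collapse = ", "), ")")
    },
    cmp = paste(deparse_blstl(n$lhs), n$op, deparse_blstl(n$rhs)),
    mcmp = paste(n$measure, n$op, deparse_blstl(n$rhs)),
    not = paste0("~(", deparse_blstl(n$child), ")"),
    and = paste0("(", deparse_blstl(n$left), ") ^ (",
                 deparse_blstl(n$right), ")"),
    or = paste0("(", deparse_blstl(n$left), ") V (",
                deparse_blstl(n$right), ")"),
    implies = paste0("(", deparse_blstl(n$left), ") => (",
                     deparse_blstl(n$right), ")"),
    iff = paste0("(", deparse_blstl(n$left), ") <=> (",
                 deparse_blstl(n$right), ")"),
    F = paste0("F [", n$a, ", ", n$b, "] (", deparse_blstl(n$child), ")"),
    G = paste0("G [", n$a, ", ", n$b, "] (", deparse_blstl(n$child), ")"),
    X = paste0("X [", n$k, "] (", deparse_blstl(n$child), ")"),
    until = paste0("(", deparse_blstl(n$left), ") U [", n$a, ", ", n$b,
                   "] (", deparse_blstl(n$right), ")"),
    stop("unknown node kind: ", n$kind))
}

deparse_collection <- function(coll) {
  if (is.null(coll$filter)) coll$which
  else paste0("filter(", coll$which, ", ", deparse_blstl(coll$filter), ")")
}
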