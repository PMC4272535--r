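#' @title BLSTL evaluation
#'
#' @description Bounded semantics of BLSTL formulas over single traces.
#' Temporal bounds are interpreted relative to the time value of the current
#' evaluation state and nest cumulatively. A missing numeric state variable
#' or a non-count statistic over an empty entity collection makes the
#' innermost enclosing comparison evaluate to false instead of aborting the
#' evaluation; a temporal window or next-state offset extending beyond the
#' end of the trace raises a `stmc_trace_too_short` error (the trace
#' provider must supply traces covering the formula horizon).
#'
#' @name blstl-evaluation
NULL

stmc_undefined <- function(msg) {
  stop(structure(class = c("stmc_undefined", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stmc_trace_too_short <- function(msg) {
  stop(structure(class = c("stmc_trace_too_short", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Convert an STML experiment into an evaluable trace
#'
#' Resolves timepoint values and reshapes each timepoint into an evaluation
#' state: its time value, its region records, its cluster records and a
#' named vector of numeric state variables.
#'
#' @param exp A [experiment()] (timepoint values are resolved if needed).
#' @return A `blstl_trace` object; `length()` returns the number of states.
#' @export
as_trace <- function(exp) {
  if (inherits(exp, "blstl_trace")) return(exp)
  stopifnot(inherits(exp, "stml_experiment"))
  exp <- resolve_timepoint_values(exp)
  states <- lapply(exp$timepoints, function(tp) {
    types <- vapply(tp$spatialEntities, function(se) se$entityType,
                    character(1))
    vars <- vapply(tp$numericStateVariables, function(v) v$value, numeric(1))
    names(vars) <- vapply(tp$numericStateVariables, function(v) v$name,
                          character(1))
    list(time = tp$value,
         regions = tp$spatialEntities[types == "region"],
         clusters = tp$spatialEntities[types == "cluster"],
         vars = vars)
  })
  structure(list(states = states,
                 times = vapply(states, function(s) s$time, integer(1))),
            class = "blstl_trace")
}

#' @export
length.blstl_trace <- function(x) length(x$states)

#' @export
print.blstl_trace <- function(x, ...) {
  cat(sprintf("BLSTL trace: %d state(s), time %d..%d\n", length(x),
              min(x$times), max(x$times)))
  invisible(x)
}

# indices of states within the window [t_i + a, t_i + b]; errors when the
# trace ends before the window does
window_indices <- function(trace, index, a, b) {
  t0 <- trace$times[index]
  n <- length(trace$states)
  if (trace$times[n] - t0 < b)
    stmc_trace_too_short(sprintf(
      "temporal window [%s, %s] relative to time %d extends beyond the trace end (time %d)",
      format(a), format(b), t0, trace$times[n]))
  which(seq_len(n) >= index &
          trace$times - t0 >= a & trace$times - t0 <= b)
}

#' Evaluate a BLSTL formula on a trace
#'
#' @param formula A formula node from [parse_pblstl()] (the `$formula` of a
#'   statement) or a whole `pblstl_statement` (its formula is used).
#' @param trace A `blstl_trace` from [as_trace()] (or an experiment, which
#'   is converted).
#' @param index 1-based state index at which to evaluate (default 1, the
#'   start of the trace).
#' @return Logical truth value.
#' @export
evaluate_blstl <- function(formula, trace, index = 1L) {
  if (inherits(formula, "pblstl_statement")) formula <- formula$formula
  trace <- as_trace(trace)
  n <- length(trace$states)
  if (index < 1L || index > n)
    stop(sprintf("state index %d outside the trace (1..%d)", index, n),
         call. = FALSE)
  eval_formula(formula, trace, as.integer(index))
}

eval_formula <- function(node, trace, i) {
  switch(node$kind,
    cmp = eval_comparison(node, trace, i),
    not = !eval_formula(node$child, trace, i),
    and = eval_formula(node$left, trace, i) &&
      eval_formula(node$right, trace, i),
    or = eval_formula(node$left, trace, i) ||
      eval_formula(node$right, trace, i),
    implies = !eval_formula(node$left, trace, i) ||
      eval_formula(node$right, trace, i),
    iff = eval_formula(node$left, trace, i) ==
      eval_formula(node$right, trace, i),
    F = {
      js <- window_indices(trace, i, node$a, node$b)
      any(vapply(js, function(j) eval_formula(node$child, trace, j),
                 logical(1)))
    },
    G = {
      js <- window_indices(trace, i, node$a, node$b)
      all(vapply(js, function(j) eval_formula(node$child, trace, j),
                 logical(1)))
    },
    until = {
      js <- window_indices(trace, i, node$a, node$b)
      for (j in js) {
        if (eval_formula(node$right, trace, j)) {
          pre <- if (j > i) i:(j - 1L) else integer(0)
          if (all(vapply(pre, function(k)
            eval_formula(node$left, trace, k), logical(1))))
            return(TRUE)
        }
      }
      FALSE
    },
    X = {
      j <- i + node$k
      if (j > length(trace$states))
        stmc_trace_too_short(sprintf(
          "X[%d] at state %d exceeds the trace length %d",
          node$k, i, length(trace$states)))
      eval_formula(node$child, trace, j)
    },
    stop("not a Boolean BLSTL node: ", node$kind))
}

# Comparisons absorb 'undefined' signals (missing variable, empty
# collection) and NaN operands by evaluating to FALSE.
eval_comparison <- function(node, trace, i) {
  res <- tryCatch({
    lhs <- eval_numeric(node$lhs, trace, i)
    rhs <- eval_numeric(node$rhs, trace, i)
    compare_values(lhs, rhs, node$op)
  }, stmc_undefined = function(e) FALSE)
  if (is.na(res)) FALSE else res
}

compare_values <- function(lhs, rhs, op) {
  switch(op,
    "<" = lhs < rhs,
    "<=" = lhs <= rhs,
    "=" = abs(lhs - rhs) <= 1e-9,
    ">=" = lhs >= rhs,
    ">" = lhs > rhs)
}

#' Evaluate a numeric BLSTL expression on a trace
#'
#' @param expr A numeric node of the BLSTL syntax tree.
#' @param trace A `blstl_trace`.
#' @param index 1-based state index.
#' @return Numeric value. Signals a `stmc_undefined` condition for missing
#'   state variables or non-count statistics over empty collections and a
#'   `stmc_trace_too_short` error when `d(...)` is applied at the final
#'   state.
#' @export
evaluate_numeric <- function(expr, trace, index = 1L) {
  trace <- as_trace(trace)
  eval_numeric(expr, trace, as.integer(index))
}

eval_numeric <- function(node, trace, i) {
  switch(node$kind,
    num = node$value,
    var = {
      vars <- trace$states[[i]]$vars
      if (is.null(vars) || !node$name %in% names(vars))
        stmc_undefined(sprintf(
          "numeric state variable '%s' missing at state %d (time %d)",
          node$name, i, trace$times[i]))
      unname(vars[[node$name]])
    },
    diff = {
      if (i + 1L > length(trace$states))
        stmc_trace_too_short(sprintf(
          "difference operator d(...) applied at the final state (index %d)",
          i))
      eval_numeric(node$child, trace, i + 1L) -
        eval_numeric(node$child, trace, i)
    },
    unary = apply_unary(node$fn, eval_numeric(node$child, trace, i)),
    binary = apply_binary(node$fn,
                          eval_numeric(node$left, trace, i),
                          eval_numeric(node$right, trace, i)),
    stat = {
      coll <- resolve_collection(node$collection, trace, i)
      if (node$fn == "covariance") {
        coll2 <- resolve_collection(node$collection2, trace, i)
        apply_statistic("covariance", coll, node$measure,
                        entities2 = coll2, measure2 = node$measure2)
      } else {
        apply_statistic(node$fn, coll, node$measure, q = node$q)
      }
    },
    stop("not a numeric BLSTL node: ", node$kind))
}

apply_unary <- function(fn, x) {
  switch(fn,
    abs = abs(x), ceil = ceiling(x), floor = floor(x),
    round = round_half_up(x), sign = sign(x), sqrt = sqrt(x),
    trunc = trunc(x), negate = -x,
    stop("unknown unary function: ", fn))
}

apply_binary <- function(fn, x, y) {
  switch(fn,
    add = x + y, subtract = x - y, multiply = x * y, divide = x / y,
    power = x^y, min = min(x, y), max = max(x, y),
    stop("unknown binary function: ", fn))
}

resolve_collection <- function(coll, trace, i) {
  entities <- trace$states[[i]][[coll$which]]
  if (is.null(coll$filter)) entities
  else filter_entities(entities, coll$filter)
}

#' Filter spatial entities by a measure constraint
#'
#' Keeps the entities whose spatial measures satisfy a Boolean constraint
#' tree over measure-vs-numeric comparisons, preserving order. The filter
#' is idempotent and `filter(x, always-true)` returns `x` unchanged.
#'
#' @param entities List of spatial entity records (or measure lists).
#' @param constraint Constraint node (from the `filter(...)` syntax of
#'   [parse_pblstl()]).
#' @return The filtered sublist.
#' @export
filter_entities <- function(entities, constraint) {
  Filter(function(e) eval_constraint(constraint, e), entities)
}

eval_constraint <- function(node, entity) {
  switch(node$kind,
    mcmp = {
      val <- entity[[node$measure]]
      if (is.null(val) || is.na(val)) return(FALSE)
      rhs <- eval_const(node$rhs)
      res <- compare_values(val, rhs, node$op)
      if (is.na(res)) FALSE else res
    },
    not = !eval_constraint(node$child, entity),
    and = eval_constraint(node$left, entity) &&
      eval_constraint(node$right, entity),
    or = eval_constraint(node$left, entity) ||
      eval_constraint(node$right, entity),
    implies = !eval_constraint(node$left, entity) ||
      eval_constraint(node$right, entity),
    iff = eval_constraint(node$left, entity) ==
      eval_constraint(node$right, entity),
    stop("invalid constraint node: ", node$kind))
}

eval_const <- function(node) {
  switch(node$kind,
    num = node$value,
    unary = apply_unary(node$fn, eval_const(node$child)),
    binary = apply_binary(node$fn, eval_const(node$left),
                          eval_const(node$right)),
    stop("non-constant expression in filter constraint"))
}

#' Apply a statistical function to an entity collection
#'
#' `count` returns the cardinality (0 for an empty collection). The
#' reducers (`mean`, `median`, `mode`, `min`, `max`, `sum`, `stdev`) apply
#' to the named spatial measure; `percentile` uses the nearest-rank
#' definition; `covariance` pairs two collections in canonical detection
#' order, truncating to the shorter one (with a warning when cardinalities
#' differ). Non-count statistics over empty collections signal
#' `stmc_undefined`, which makes the enclosing comparison false.
#'
#' @param stat Statistic name.
#' @param entities List of spatial entity records.
#' @param measure Spatial measure name (all statistics except `count`).
#' @param q Percentile in \[0, 100\] (`percentile` only).
#' @param entities2,measure2 Second collection and measure (`covariance`).
#' @return Numeric value.
#' @export
apply_statistic <- function(stat, entities, measure = NULL, q = NULL,
                            entities2 = NULL, measure2 = NULL) {
  if (stat == "count") return(length(entities))
  if (!length(entities))
    stmc_undefined(sprintf("statistic '%s' over an empty collection", stat))
  values <- vapply(entities, function(e) as.numeric(e[[measure]]),
                   numeric(1))
  switch(stat,
    mean = mean(values),
    median = stats::median(values),
    min = min(values),
    max = max(values),
    sum = sum(values),
    stdev = if (length(values) < 2L) 0 else stats::sd(values),
    mode = {
      tab <- sort(table(values), decreasing = TRUE)
      as.numeric(names(tab)[tab == max(tab)][1L])
    },
    percentile = {
      if (is.null(q) || q < 0 || q > 100)
        stop("percentile requires q in [0, 100]", call. = FALSE)
      sorted <- sort(values)
      rank <- max(1L, ceiling(q / 100 * length(sorted)))
      sorted[rank]
    },
    covariance = {
      if (is.null(entities2) || !length(entities2))
        stmc_undefined("covariance over an empty collection")
      values2 <- vapply(entities2, function(e) as.numeric(e[[measure2]]),
                        numeric(1))
      n <- min(length(values), length(values2))
      if (length(values) != length(values2))
        warning(sprintf(
          "covariance: collections differ in cardinality (%d vs %d); %s",
          length(values), length(values2),
          "pairing in canonical order and truncating to the shorter"),
          call. = FALSE)
      if (n < 2L)
        stmc_undefined("covariance requires at least two paired entities")
      stats::cov(values[seq_len(n)], values2[seq_len(n)])
    },
    stop("unknown statistic: ", stat))
}
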