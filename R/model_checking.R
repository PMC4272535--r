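#' @title Approximate probabilistic model checking
#'
#' @description Decides PBLSTL statements `P ~ theta [ psi ]` over
#' collections of traces using five approximate algorithms: the Wald
#' sequential probability ratio test with an indifference region
#' (frequentist hypothesis testing), fixed-sample estimation with the
#' Chernoff-Hoeffding bound (frequentist estimation), sequential Bayes
#' factor testing and Bayesian credible-interval estimation with a Beta
#' prior, and probabilistic black-box checking with an exact binomial-tail
#' p-value. Sequential methods that exhaust the trace supply before
#' reaching a decision fall back to the black-box verdict computed from the
#' observations gathered so far.
#'
#' @name model-checking
NULL

#' Model checker configuration
#'
#' @param method One of `"frequentist_hypothesis"` (SPRT),
#'   `"frequentist_estimate"` (Chernoff-Hoeffding), `"bayesian_hypothesis"`
#'   (Bayes factor), `"bayesian_estimate"` (posterior mean and credible
#'   mass) or `"black_box"`.
#' @param typeIError,typeIIError SPRT error bounds alpha and beta, in (0, 1).
#' @param indifferenceHalfWidth Half-width of the SPRT indifference region
#'   around theta; must satisfy `0 < delta < min(theta, 1 - theta)` for the
#'   statement being checked.
#' @param estimateEpsilon,estimateDelta Chernoff-Hoeffding approximation
#'   bound and risk, both in (0, 1); the required sample size is
#'   `ceiling(log(2 / delta) / (2 * epsilon^2))`.
#' @param bayesFactorThreshold Decision threshold T > 1 on the Bayes factor.
#' @param priorAlpha,priorBeta Beta prior parameters (> 0).
#' @param credibleHalfWidth,credibleCoverage Bayesian-estimate stopping
#'   rule: stop when the posterior mass of `(mean - w, mean + w)` reaches
#'   the coverage c, both in (0, 1).
#' @param maxTraces Maximum number of traces to consume (`Inf` for
#'   unbounded); sequential methods reaching it without a decision fall
#'   back to the black-box verdict.
#' @param maxSeconds Optional wall-clock bound with the same fallback.
#' @return A `checker_config` object.
#' @export
checker_config <- function(method = c("frequentist_hypothesis",
                                      "frequentist_estimate",
                                      "bayesian_hypothesis",
                                      "bayesian_estimate",
                                      "black_box"),
                           typeIError = 0.05, typeIIError = 0.05,
                           indifferenceHalfWidth = 0.05,
                           estimateEpsilon = 0.05, estimateDelta = 0.05,
                           bayesFactorThreshold = 100,
                           priorAlpha = 1, priorBeta = 1,
                           credibleHalfWidth = 0.05,
                           credibleCoverage = 0.95,
                           maxTraces = Inf, maxSeconds = NULL) {
  method <- match.arg(method)
  in_unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  stopifnot(in_unit(typeIError), in_unit(typeIIError),
            in_unit(estimateEpsilon), in_unit(estimateDelta),
            in_unit(credibleHalfWidth), in_unit(credibleCoverage),
            indifferenceHalfWidth > 0,
            bayesFactorThreshold > 1,
            priorAlpha > 0, priorBeta > 0,
            maxTraces >= 1)
  structure(list(method = method,
                 typeIError = typeIError, typeIIError = typeIIError,
                 indifferenceHalfWidth = indifferenceHalfWidth,
                 estimateEpsilon = estimateEpsilon,
                 estimateDelta = estimateDelta,
                 bayesFactorThreshold = bayesFactorThreshold,
                 priorAlpha = priorAlpha, priorBeta = priorBeta,
                 credibleHalfWidth = credibleHalfWidth,
                 credibleCoverage = credibleCoverage,
                 maxTraces = maxTraces, maxSeconds = maxSeconds),
            class = "checker_config")
}

checking_result <- function(verdict, methodUsed, nTrue, nFalse, confidence,
                            exhausted = FALSE, estimate = NA_real_) {
  structure(list(verdict = verdict, methodUsed = methodUsed,
                 nTotal = nTrue + nFalse, nTrue = nTrue, nFalse = nFalse,
                 confidence = confidence, estimate = estimate,
                 exhausted = exhausted),
            class = "checking_result")
}

#' @export
print.checking_result <- function(x, ...) {
  cat(sprintf(
    "%s  [%s]  traces: %d (%d true / %d false)  confidence: %s%s\n",
    if (x$verdict) "TRUE" else "FALSE", x$methodUsed,
    x$nTotal, x$nTrue, x$nFalse, format(x$confidence),
    if (x$exhausted) "  (trace supply exhausted; black-box fallback)" else ""))
  invisible(x)
}

# ---- trace providers -------------------------------------------------------

new_provider <- function(next_trace, description, n_available = Inf) {
  env <- new.env(parent = emptyenv())
  env$loads <- 0L
  env$next_trace_fn <- next_trace
  env$description <- description
  env$n_available <- n_available
  class(env) <- "trace_provider"
  env
}

#' @export
print.trace_provider <- function(x, ...) {
  cat(sprintf("trace provider: %s (%d trace(s) consumed)\n",
              x$description, x$loads))
  invisible(x)
}

provider_next <- function(provider) {
  tr <- provider$next_trace_fn(provider$loads + 1L)
  if (is.null(tr)) return(NULL)
  provider$loads <- provider$loads + 1L
  as_trace(tr)
}

#' Trace provider over a directory of STML files
#'
#' Files are consumed in canonical (lexicographic file name) order, each
#' read and parsed exactly once.
#'
#' @param dir Directory containing `.xml`/`.stml` files.
#' @param pattern File name pattern (default STML/XML extensions).
#' @return A `trace_provider`.
#' @export
trace_provider_directory <- function(dir, pattern = "\\.(xml|stml)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files))
    stop(sprintf("no STML files found in '%s'", dir), call. = FALSE)
  new_provider(function(i) {
    if (i > length(files)) NULL else read_stml(files[i])
  }, sprintf("directory %s (%d files)", dir, length(files)),
  n_available = length(files))
}

#' Trace provider over in-memory experiments
#'
#' @param experiments List of [experiment()] objects or `blstl_trace`s.
#' @return A `trace_provider`.
#' @export
trace_provider_memory <- function(experiments) {
  stopifnot(length(experiments) >= 1)
  new_provider(function(i) {
    if (i > length(experiments)) NULL else experiments[[i]]
  }, sprintf("in-memory collection (%d traces)", length(experiments)),
  n_available = length(experiments))
}

#' Trace provider backed by a generator function
#'
#' On-demand trace generation: `fn(i, seed)` must return one experiment or
#' trace per invocation `i = 1, 2, ...`. Each invocation receives a
#' distinct seed derived from `seed + i - 1`, making the observation
#' sequence reproducible.
#'
#' @param fn Function of `(i, seed)` returning an [experiment()] (or `NULL`
#'   to signal exhaustion).
#' @param seed Master seed.
#' @return A `trace_provider`.
#' @export
trace_provider_function <- function(fn, seed = 1L) {
  new_provider(function(i) fn(i, seed + i - 1L),
               "on-demand generator function")
}

#' Trace provider backed by a generator script
#'
#' Runs `command --seed <derived seed> --out <tmpfile>` once per requested
#' trace; the script must write a single STML file to the given path.
#'
#' @param command Path of the executable generator script.
#' @param seed Master seed; invocation `i` receives `seed + i - 1`.
#' @return A `trace_provider`.
#' @export
trace_provider_script <- function(command, seed = 1L) {
  new_provider(function(i) {
    out <- tempfile(fileext = ".xml")
    status <- system2(command,
                      c("--seed", as.character(seed + i - 1L), "--out", out))
    if (status != 0 || !file.exists(out))
      stop(sprintf("trace generator '%s' failed (exit status %s)",
                   command, status), call. = FALSE)
    on.exit(unlink(out))
    read_stml(out)
  }, sprintf("generator script %s", command))
}

#' Draw one Bernoulli observation from a trace provider
#'
#' Loads the next trace in canonical order and evaluates the BLSTL formula
#' on it from its first state.
#'
#' @param provider A `trace_provider`.
#' @param formula BLSTL formula node or `pblstl_statement`.
#' @return `TRUE`/`FALSE`, or `NULL` when the provider is exhausted.
#' @export
sample_next <- function(provider, formula) {
  tr <- provider_next(provider)
  if (is.null(tr)) return(NULL)
  evaluate_blstl(formula, tr)
}

# ---- sequential testers ----------------------------------------------------
# Each tester is an environment with $update(x) and $finalize(); $decided /
# $result are set once a verdict is reached. The single-statement checkers
# and the one-pass multi-statement checker share these state machines, so
# both routes produce identical results for the same observation sequence.

comparator_holds <- function(phat, comparator, theta) {
  switch(comparator,
    "<" = phat < theta, "<=" = phat <= theta,
    ">" = phat > theta, ">=" = phat >= theta)
}

# `closed` comparators accept equality; used for the black-box tie rule:
# phat == theta resolves in favour of the comparator's closed side.
black_box_verdict <- function(nTrue, n, comparator, theta) {
  phat <- nTrue / n
  comparator_holds(phat, comparator, theta)
}

black_box_pvalue <- function(nTrue, n, comparator, theta, verdict) {
  # direction of the claim supported by the verdict: does it assert that
  # p is at least theta, or at most theta?
  claims_high <- (comparator %in% c(">", ">=")) == verdict
  if (claims_high) stats::pbinom(nTrue - 1, n, theta, lower.tail = FALSE)
  else stats::pbinom(nTrue, n, theta)
}

make_tester <- function(statement, cfg) {
  env <- new.env(parent = emptyenv())
  env$nTrue <- 0L
  env$nFalse <- 0L
  env$decided <- FALSE
  env$result <- NULL
  theta <- statement$theta
  comparator <- statement$comparator

  finalize_black_box <- function(exhausted = TRUE, method = "black_box") {
    n <- env$nTrue + env$nFalse
    if (n == 0L)
      stop("no traces available: the statement is undecidable",
           call. = FALSE)
    verdict <- black_box_verdict(env$nTrue, n, comparator, theta)
    env$result <- checking_result(
      verdict, method, env$nTrue, env$nFalse,
      black_box_pvalue(env$nTrue, n, comparator, theta, verdict),
      exhausted = exhausted, estimate = env$nTrue / n)
    env$decided <- TRUE
    invisible(env$result)
  }
  env$finalize <- finalize_black_box

  if (cfg$method == "frequentist_hypothesis") {
    delta <- cfg$indifferenceHalfWidth
    if (delta >= min(theta, 1 - theta))
      stop(sprintf(
        "indifference half-width %.4g must be < min(theta, 1 - theta) = %.4g",
        delta, min(theta, 1 - theta)), call. = FALSE)
    p0 <- theta + delta
    p1 <- theta - delta
    logA <- log((1 - cfg$typeIIError) / cfg$typeIError)
    logB <- log(cfg$typeIIError / (1 - cfg$typeIError))
    env$llr <- 0
    env$update <- function(x) {
      env$llr <- env$llr +
        if (x) log(p1 / p0) else log((1 - p1) / (1 - p0))
      if (x) env$nTrue <- env$nTrue + 1L else env$nFalse <- env$nFalse + 1L
      if (env$llr <= logB) {
        # accept H0: p >= theta + delta
        verdict <- comparator %in% c(">", ">=")
        env$result <- checking_result(verdict, "frequentist_hypothesis",
                                      env$nTrue, env$nFalse, env$llr)
        env$decided <- TRUE
      } else if (env$llr >= logA) {
        # accept H1: p <= theta - delta
        verdict <- comparator %in% c("<", "<=")
        env$result <- checking_result(verdict, "frequentist_hypothesis",
                                      env$nTrue, env$nFalse, env$llr)
        env$decided <- TRUE
      }
      invisible(env$decided)
    }
  } else if (cfg$method == "frequentist_estimate") {
    n_req <- chernoff_sample_size(cfg$estimateEpsilon, cfg$estimateDelta)
    env$update <- function(x) {
      if (x) env$nTrue <- env$nTrue + 1L else env$nFalse <- env$nFalse + 1L
      if (env$nTrue + env$nFalse >= n_req) {
        phat <- env$nTrue / (env$nTrue + env$nFalse)
        env$result <- checking_result(
          comparator_holds(phat, comparator, theta),
          "frequentist_estimate", env$nTrue, env$nFalse, cfg$estimateDelta,
          estimate = phat)
        env$decided <- TRUE
      }
      invisible(env$decided)
    }
  } else if (cfg$method == "bayesian_hypothesis") {
    a <- cfg$priorAlpha; b <- cfg$priorBeta
    Tthr <- cfg$bayesFactorThreshold
    env$update <- function(x) {
      if (x) env$nTrue <- env$nTrue + 1L else env$nFalse <- env$nFalse + 1L
      B <- bayes_factor(env$nTrue, env$nFalse, comparator, theta, a, b)
      if (B >= Tthr || B <= 1 / Tthr) {
        env$result <- checking_result(B >= Tthr, "bayesian_hypothesis",
                                      env$nTrue, env$nFalse, B)
        env$decided <- TRUE
      }
      invisible(env$decided)
    }
  } else if (cfg$method == "bayesian_estimate") {
    a <- cfg$priorAlpha; b <- cfg$priorBeta
    w <- cfg$credibleHalfWidth; cc <- cfg$credibleCoverage
    env$update <- function(x) {
      if (x) env$nTrue <- env$nTrue + 1L else env$nFalse <- env$nFalse + 1L
      n <- env$nTrue + env$nFalse
      phat <- (a + env$nTrue) / (a + b + n)
      mass <- stats::pbeta(min(1, phat + w), a + env$nTrue,
                           b + env$nFalse) -
        stats::pbeta(max(0, phat - w), a + env$nTrue, b + env$nFalse)
      if (mass >= cc) {
        env$result <- checking_result(
          comparator_holds(phat, comparator, theta),
          "bayesian_estimate", env$nTrue, env$nFalse, mass,
          estimate = phat)
        env$decided <- TRUE
      }
      invisible(env$decided)
    }
  } else {  # black_box: consume everything, decide at exhaustion
    env$update <- function(x) {
      if (x) env$nTrue <- env$nTrue + 1L else env$nFalse <- env$nFalse + 1L
      invisible(FALSE)
    }
    env$finalize <- function(exhausted = TRUE, method = "black_box")
      finalize_black_box(exhausted = FALSE, method = method)
  }
  env
}

#' Chernoff-Hoeffding sample size
#'
#' Number of observations required so that the empirical estimate deviates
#' from the true probability by at least `epsilon` with probability at most
#' `delta`: `ceiling(log(2 / delta) / (2 * epsilon^2))`.
#'
#' @param epsilon Approximation bound in (0, 1).
#' @param delta Risk bound in (0, 1).
#' @return Integer sample size.
#' @export
chernoff_sample_size <- function(epsilon, delta) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop("'delta' must lie strictly inside (0, 1)", call. = FALSE)
  as.integer(ceiling(log(2 / delta) / (2 * epsilon^2)))
}

#' Bayes factor for a probability-threshold hypothesis
#'
#' Posterior odds over prior odds of the hypothesis `{p : p ~ theta}`
#' (where `~` is the statement comparator) under a Beta(a, b) prior after
#' observing `nTrue` successes and `nFalse` failures.
#'
#' @param nTrue,nFalse Observation counts.
#' @param comparator Statement comparator.
#' @param theta Probability threshold.
#' @param a,b Beta prior parameters.
#' @return The Bayes factor (possibly `Inf`).
#' @export
bayes_factor <- function(nTrue, nFalse, comparator, theta, a = 1, b = 1) {
  upper <- comparator %in% c(">", ">=")
  prior0 <- if (upper) stats::pbeta(theta, a, b, lower.tail = FALSE)
            else stats::pbeta(theta, a, b)
  post0 <- if (upper)
    stats::pbeta(theta, a + nTrue, b + nFalse, lower.tail = FALSE)
  else stats::pbeta(theta, a + nTrue, b + nFalse)
  odds <- function(p) {
    if (p >= 1) Inf else if (p <= 0) 0 else p / (1 - p)
  }
  po <- odds(post0); pr <- odds(prior0)
  if (pr == 0) return(Inf)
  if (is.infinite(pr)) return(if (is.infinite(po)) 1 else 0)
  po / pr
}

# ---- checkers --------------------------------------------------------------

run_sequential <- function(statement, provider, cfg) {
  check_specification(list(statement), provider, cfg)[[1]]
}

#' Check a statement with the sequential probability ratio test
#'
#' Wald SPRT of H0: `p >= theta + delta` against H1: `p <= theta - delta`
#' with type I/II error bounds alpha and beta. The verdict maps acceptance
#' of H0 to `TRUE` for `>=`/`>` statements and acceptance of H1 to `TRUE`
#' for `<`/`<=` statements. If the provider is exhausted before a decision
#' the black-box verdict over the gathered observations is returned with
#' `methodUsed = "black_box"` and `exhausted = TRUE`.
#'
#' @param statement A `pblstl_statement`.
#' @param provider A `trace_provider`.
#' @param cfg A [checker_config()] (method forced to SPRT).
#' @return A `checking_result`.
#' @export
check_sprt <- function(statement, provider, cfg = checker_config()) {
  cfg$method <- "frequentist_hypothesis"
  run_sequential(statement, provider, cfg)
}

#' Check a statement with the Chernoff-Hoeffding estimate
#'
#' Draws the fixed sample size implied by `estimateEpsilon` and
#' `estimateDelta`, then compares the empirical probability with theta.
#'
#' @inheritParams check_sprt
#' @return A `checking_result` (confidence is the risk bound delta).
#' @export
check_chernoff <- function(statement, provider, cfg = checker_config()) {
  cfg$method <- "frequentist_estimate"
  chernoff_sample_size(cfg$estimateEpsilon, cfg$estimateDelta)  # validates
  run_sequential(statement, provider, cfg)
}

#' Check a statement by sequential Bayes factor testing
#'
#' After each observation the Bayes factor of the hypothesis
#' `{p : p ~ theta}` under the Beta prior is computed from the posterior;
#' sampling stops when it reaches `bayesFactorThreshold` (verdict `TRUE`)
#' or its reciprocal (verdict `FALSE`).
#'
#' @inheritParams check_sprt
#' @return A `checking_result` (confidence is the Bayes factor).
#' @export
check_bayesian_hypothesis <- function(statement, provider,
                                      cfg = checker_config()) {
  cfg$method <- "bayesian_hypothesis"
  run_sequential(statement, provider, cfg)
}

#' Check a statement by Bayesian estimation
#'
#' Samples until the posterior mass of the interval `(mean - w, mean + w)`
#' around the posterior mean reaches the configured coverage, then compares
#' the posterior mean with theta.
#'
#' @inheritParams check_sprt
#' @return A `checking_result` (confidence is the achieved coverage).
#' @export
check_bayesian_estimate <- function(statement, provider,
                                    cfg = checker_config()) {
  cfg$method <- "bayesian_estimate"
  run_sequential(statement, provider, cfg)
}

#' Black-box check over a fixed set of observations
#'
#' Computes the verdict `phat ~ theta` from a fixed number of observations
#' (never requesting more traces) together with a one-sided exact binomial
#' tail p-value under `p = theta`: the probability of an outcome at least
#' as favourable to the verdict as the one observed. Small values indicate
#' strong support. A tie `phat == theta` resolves in favour of the
#' comparator's closed side.
#'
#' @param statement A `pblstl_statement`.
#' @param observations Logical vector of per-trace truth values, or a
#'   `trace_provider` to be drained (up to `cfg$maxTraces`).
#' @param cfg A [checker_config()].
#' @return A `checking_result`.
#' @export
check_black_box <- function(statement, observations,
                            cfg = checker_config()) {
  if (inherits(observations, "trace_provider")) {
    obs <- logical(0)
    while (length(obs) < cfg$maxTraces) {
      x <- sample_next(observations, statement$formula)
      if (is.null(x)) break
      obs <- c(obs, x)
    }
    observations <- obs
  }
  n <- length(observations)
  if (n == 0L)
    stop("no observations available: the statement is undecidable",
         call. = FALSE)
  nTrue <- sum(observations)
  verdict <- black_box_verdict(nTrue, n, statement$comparator,
                               statement$theta)
  checking_result(verdict, "black_box", nTrue, as.integer(n - nTrue),
                  black_box_pvalue(nTrue, n, statement$comparator,
                                   statement$theta, verdict),
                  estimate = nTrue / n)
}

#' Check a full specification in a single pass over the traces
#'
#' Evaluates every statement against each loaded trace exactly once: a
#' trace is read a single time and fed to all statements whose sequential
#' tests are still undecided. Per-statement tests advance independently, so
#' the results are identical to checking each statement alone against the
#' same ordered provider. Statements still undecided when the provider is
#' exhausted (or `maxTraces`/`maxSeconds` is reached) receive the black-box
#' fallback verdict over their gathered observations.
#'
#' @param statements List of `pblstl_statement`s (at least one).
#' @param provider A `trace_provider`.
#' @param cfg A [checker_config()].
#' @return List of `checking_result`s, one per statement.
#' @export
check_specification <- function(statements, provider,
                                cfg = checker_config()) {
  if (!length(statements))
    stop("the specification must contain at least one statement",
         call. = FALSE)
  stopifnot(inherits(provider, "trace_provider"))
  testers <- lapply(statements, make_tester, cfg = cfg)
  start <- Sys.time()
  consumed <- 0L
  exhausted_provider <- FALSE
  while (any(!vapply(testers, function(tt) tt$decided, logical(1)))) {
    if (consumed >= cfg$maxTraces) break
    if (!is.null(cfg$maxSeconds) &&
        as.numeric(difftime(Sys.time(), start, units = "secs")) >
        cfg$maxSeconds) break
    tr <- provider_next(provider)
    if (is.null(tr)) { exhausted_provider <- TRUE; break }
    consumed <- consumed + 1L
    for (k in seq_along(testers)) {
      if (testers[[k]]$decided) next
      testers[[k]]$update(evaluate_blstl(statements[[k]]$formula, tr))
    }
  }
  lapply(testers, function(tt) {
    if (!tt$decided) tt$finalize(exhausted = exhausted_provider)
    tt$result
  })
}
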