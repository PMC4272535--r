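test_that("SPRT decision counts match the Wald closed forms", {
  # theta 0.9, delta 0.05, alpha = beta = 0.05: p0 = 0.95, p1 = 0.85
  n_true <- ceiling(log(0.05 / 0.95) / log(0.85 / 0.95))
  expect_identical(n_true, 27)
  r <- check_sprt(stmt(), obs_provider(rep(TRUE, 50)))
  expect_true(r$verdict)
  expect_identical(r$methodUsed, "frequentist_hypothesis")
  expect_identical(r$nTotal, as.integer(n_true))
  expect_identical(r$nTotal, r$nTrue + r$nFalse)

  n_false <- ceiling(log(0.95 / 0.05) / log(0.15 / 0.05))
  r2 <- check_sprt(stmt(), obs_provider(rep(FALSE, 50)))
  expect_false(r2$verdict)
  expect_identical(r2$nTotal, as.integer(n_false))

  # < statements map acceptance of H1 to TRUE
  r3 <- check_sprt(stmt("P < 0.9 [ {A} > 1 ]"), obs_provider(rep(FALSE, 50)))
  expect_true(r3$verdict)
  expect_error(check_sprt(stmt("P >= 0.97 [ {A} > 1 ]"),
                          obs_provider(rep(TRUE, 5))), "indifference")
})

test_that("exhaustion falls back to black-box on the gathered observations", {
  r <- check_sprt(stmt(), obs_provider(c(TRUE, TRUE, FALSE)))
  expect_identical(r$methodUsed, "black_box")
  expect_true(r$exhausted)
  expect_identical(r$nTotal, 3L)
  expect_identical(r$nTrue, 2L)
  # verdict equals the direct black-box verdict on the same observations
  bb <- check_black_box(stmt(), c(TRUE, TRUE, FALSE))
  expect_identical(r$verdict, bb$verdict)
  expect_equal(r$confidence, bb$confidence)
})

test_that("SPRT empirical error rates stay within the nominal bounds", {
  st <- stmt("P >= 0.5 [ {A} > 1 ]")  # theta 0.5, indifference 0.05
  run_one <- function(p, seed) {
    set.seed(seed)
    xs <- runif(100) < p
    check_sprt(st, obs_provider(xs))$verdict
  }
  # true p = 0.75 >> p0 = 0.55: rejecting (verdict FALSE) is a type I error
  err1 <- mean(!vapply(1:200, function(i) run_one(0.75, i), logical(1)))
  expect_lte(err1, 0.05 + 0.03)
  # true p = 0.25 << p1 = 0.45: accepting (verdict TRUE) is a type II error
  err2 <- mean(vapply(1:200, function(i) run_one(0.25, 1000 + i),
                      logical(1)))
  expect_lte(err2, 0.05 + 0.03)
})

test_that("Chernoff-Hoeffding sample size and coverage behave as bounded", {
  expect_identical(chernoff_sample_size(0.05, 0.05), 738L)
  expect_identical(chernoff_sample_size(0.1, 0.1), 150L)
  expect_error(chernoff_sample_size(1, 0.05), "epsilon")
  expect_error(chernoff_sample_size(0.05, 0), "delta")

  st <- stmt()
  r <- check_chernoff(st, obs_provider(rep(TRUE, 738)))
  expect_true(r$verdict)
  expect_identical(r$nTotal, 738L)
  expect_equal(r$estimate, 1)
  expect_equal(r$confidence, 0.05)

  # coverage with a loose epsilon so each repetition is cheap:
  # eps = delta = 0.2 requires n = 29
  cfg <- checker_config(method = "frequentist_estimate",
                        estimateEpsilon = 0.2, estimateDelta = 0.2)
  n_req <- chernoff_sample_size(0.2, 0.2)
  miss <- vapply(1:200, function(i) {
    set.seed(i)
    xs <- runif(n_req) < 0.5
    r <- check_chernoff(stmt("P >= 0.5 [ {A} > 1 ]"), obs_provider(xs), cfg)
    abs(r$estimate - 0.5) >= 0.2
  }, logical(1))
  expect_lte(mean(miss), 0.2 + 0.03)
})

test_that("Bayesian machinery matches the conjugate Beta formulas", {
  # prior = posterior with no data: Bayes factor 1
  expect_equal(bayes_factor(0, 0, ">=", 0.5), 1)
  # monotone in nTrue at fixed nTotal, against a numeric-integration oracle
  oracle_B <- function(x, n, theta, a = 1, b = 1) {
    post <- stats::integrate(function(p)
      stats::dbeta(p, a + x, b + n - x), theta, 1)$value
    prior <- stats::integrate(function(p) stats::dbeta(p, a, b),
                              theta, 1)$value
    (post / (1 - post)) / (prior / (1 - prior))
  }
  Bs <- vapply(0:10, function(x) bayes_factor(x, 10 - x, ">=", 0.7),
               numeric(1))
  expect_true(all(diff(Bs) > 0))
  for (x in c(2, 5, 8))
    expect_equal(bayes_factor(x, 10 - x, ">=", 0.7),
                 oracle_B(x, 10, 0.7), tolerance = 1e-6)

  # all-true stream at theta 0.9, T = 100: first decision where the
  # posterior tail mass yields B >= 100, found by the incomplete-beta oracle
  n_star <- which(vapply(1:200, function(n)
    oracle_B(n, n, 0.9) >= 100, logical(1)))[1]
  r <- check_bayesian_hypothesis(stmt(), obs_provider(rep(TRUE, 300)),
                                 checker_config(method = "bayesian_hypothesis"))
  expect_true(r$verdict)
  expect_identical(r$nTotal, as.integer(n_star))
  expect_gte(r$confidence, 100)

  # posterior mean (a + x) / (a + b + n), uniform prior
  cfg <- checker_config(method = "bayesian_estimate",
                        credibleHalfWidth = 0.26, credibleCoverage = 0.9)
  r2 <- check_bayesian_estimate(stmt("P >= 0.5 [ {A} > 1 ]"),
                                obs_provider(c(TRUE, TRUE, FALSE, TRUE,
                                               rep(c(TRUE, FALSE), 10))),
                                cfg)
  expect_equal(r2$estimate, (1 + r2$nTrue) / (2 + r2$nTotal))
  # posterior mass of the credible window reached the coverage
  expect_gte(r2$confidence, 0.9)

  # w = 0.5, c = 0.5 terminates after a single observation (uniform prior)
  cfg1 <- checker_config(method = "bayesian_estimate",
                         credibleHalfWidth = 0.5, credibleCoverage = 0.5)
  r3 <- check_bayesian_estimate(stmt("P >= 0.5 [ {A} > 1 ]"),
                                obs_provider(rep(TRUE, 10)), cfg1)
  expect_identical(r3$nTotal, 1L)

  # posterior mean converges to the truth
  set.seed(1234)
  xs <- runif(2000) < 0.3
  cfgc <- checker_config(method = "bayesian_estimate",
                         credibleHalfWidth = 0.02,
                         credibleCoverage = 0.95)
  rc <- check_bayesian_estimate(stmt("P >= 0.5 [ {A} > 1 ]"),
                                obs_provider(xs), cfgc)
  expect_lt(abs(rc$estimate - 0.3), 0.05)
})

test_that("black-box verdicts and p-values follow the exact binomial tail", {
  st <- stmt("P >= 0.5 [ {A} > 1 ]")
  r <- check_black_box(st, rep(TRUE, 10))
  expect_true(r$verdict)
  expect_equal(r$confidence, 0.5^10)
  r2 <- check_black_box(st, rep(c(TRUE, FALSE), 5))
  expect_true(r2$verdict)  # tie resolves to the closed side of >=
  expect_equal(r2$confidence, pbinom(4, 10, 0.5, lower.tail = FALSE))
  r2b <- check_black_box(stmt("P > 0.5 [ {A} > 1 ]"), rep(c(TRUE, FALSE), 5))
  expect_false(r2b$verdict)  # strict comparator: tie fails
  # exchangeability: order of observations is irrelevant
  set.seed(3)
  xs <- runif(30) < 0.6
  ra <- check_black_box(st, xs)
  rb <- check_black_box(st, rev(xs))
  expect_identical(ra$verdict, rb$verdict)
  expect_equal(ra$confidence, rb$confidence)
  expect_error(check_black_box(st, logical(0)), "no observations")
})

test_that("single-pass specification checking equals per-statement runs", {
  set.seed(8)
  xs <- runif(40) < 0.8
  exps <- lapply(xs, obs_exp)
  statements <- parse_pblstl(paste(
    "P >= 0.9 [ {A} > 1 ]",
    "P < 0.5 [ {A} > 1 ]",
    "P >= 0.6 [ {A} > 1 ]", sep = "\n"))
  cfg <- checker_config()
  joint <- check_specification(statements, trace_provider_memory(exps), cfg)
  for (k in seq_along(statements)) {
    alone <- check_specification(statements[k],
                                 trace_provider_memory(exps), cfg)[[1]]
    expect_identical(joint[[k]]$verdict, alone$verdict)
    expect_identical(joint[[k]]$nTotal, alone$nTotal)
    expect_equal(joint[[k]]$confidence, alone$confidence)
  }
  # every trace is loaded at most once in the joint pass
  prov <- trace_provider_memory(exps[1:5])
  res <- check_specification(statements[1:2], prov,
                             checker_config(method = "black_box"))
  expect_identical(prov$loads, 5L)
  expect_error(check_specification(list(), prov), "at least one")
})

test_that("providers yield deterministic canonical observation sequences", {
  exps <- lapply(c(TRUE, FALSE, TRUE), obs_exp)
  p1 <- trace_provider_memory(exps)
  f <- stmt()$formula
  expect_identical(c(sample_next(p1, f), sample_next(p1, f),
                     sample_next(p1, f)), c(TRUE, FALSE, TRUE))
  expect_null(sample_next(p1, f))

  dir <- withr::local_tempdir()
  generate_stml_dataset("chemotaxis", 2, dir, seed = 42, nTimepoints = 3,
                        nCells = 20, latticeSize = c(30, 30))
  pd <- trace_provider_directory(dir)
  s <- stmt("P > 0.5 [ count(clusters) >= 0 ]")
  expect_true(sample_next(pd, s$formula))
  expect_true(sample_next(pd, s$formula))
  expect_null(sample_next(pd, s$formula))
  expect_identical(pd$loads, 2L)

  pf <- trace_provider_function(function(i, seed) {
    if (i > 2) return(NULL)
    simple_exp(seed)  # the derived seed is visible to the generator
  }, seed = 10L)
  tr1 <- stmc:::provider_next(pf)
  tr2 <- stmc:::provider_next(pf)
  expect_equal(tr1$states[[1]]$vars[["A"]], 10)
  expect_equal(tr2$states[[1]]$vars[["A"]], 11)
  expect_null(stmc:::provider_next(pf))
})
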