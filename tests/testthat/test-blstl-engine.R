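test_that("the surface syntax of the worked example statements parses", {
  s1 <- parse_pblstl(
    "P >= 0.9 [ F [0, 100] (({cAMP} < 20) ^ (count(clusters) > 0)) ]")
  expect_length(s1, 1)
  expect_identical(s1[[1]]$comparator, ">=")
  expect_equal(s1[[1]]$theta, 0.9)
  f <- s1[[1]]$formula
  expect_identical(f$kind, "F")
  expect_equal(c(f$a, f$b), c(0, 100))
  expect_identical(f$child$kind, "and")

  s2 <- parse_pblstl("P > 0.5 [ G [5, 25] (d(mean(regions, area)) > 0) ]")
  inner <- s2[[1]]$formula$child
  expect_identical(inner$lhs$kind, "diff")
  expect_identical(inner$lhs$child$kind, "stat")

  s3 <- parse_pblstl(paste0(
    "P > 0.2 [ (count(filter(clusters, distanceFromOrigin < 10)) > 0) ",
    "U [0, 300] ({X} < 5) ]"))
  expect_identical(s3[[1]]$formula$kind, "until")
  expect_identical(s3[[1]]$formula$left$lhs$collection$filter$measure,
                   "distanceFromOrigin")
})

test_that("parse errors carry location and semantic violations are caught", {
  expect_error(parse_pblstl("P >= 1.5 [ {A} > 0 ]"),
               class = "blstl_semantic_error")
  expect_error(parse_pblstl("P >= 0 [ {A} > 0 ]"),
               class = "blstl_semantic_error")
  err <- expect_error(parse_pblstl("P >= 0.5 [ {A} >< 0 ]"),
                      class = "blstl_syntax_error")
  expect_match(conditionMessage(err), "line [0-9]+, column [0-9]+")
  expect_error(parse_pblstl("P >= 0.5 [ F [5, 2] ({A} > 0) ]"),
               class = "blstl_semantic_error")
  expect_error(parse_pblstl("P > 0.5 [ count(filter(regions, {A} > 1)) > 0 ]"),
               class = "blstl_semantic_error")
  expect_error(parse_pblstl("P > 0.5 [ mean(regions, bogus) > 0 ]"),
               class = "blstl_semantic_error")
  expect_error(parse_pblstl("   # only a comment\n"),
               class = "blstl_syntax_error")
})

test_that("temporal and numeric semantics follow the bounded definitions", {
  tr <- as_trace(simple_exp(c(1, 2, 3)))
  fml <- function(txt) parse_pblstl(paste0("P > 0.5 [ ", txt, " ]"))[[1]]$formula
  expect_true(evaluate_blstl(fml("G [0, 2] ({A} > 0)"), tr))
  expect_false(evaluate_blstl(fml("G [0, 2] ({A} > 1)"), tr))
  expect_true(evaluate_blstl(fml("F [0, 2] ({A} = 3)"), tr))
  expect_true(evaluate_blstl(fml("({A} < 3) U [0, 2] ({A} = 3)"), tr))
  expect_true(evaluate_blstl(fml("X [2] ({A} = 3)"), tr))
  expect_true(evaluate_blstl(fml("d({A}) = 1"), tr))
  expect_true(evaluate_blstl(fml("sqrt(add({A}, 8)) = 3"), tr))
  expect_equal(evaluate_numeric(fml("{A} = 0")$lhs, tr, 3), 3)
  # windows beyond the trace end are an error, not false
  expect_error(evaluate_blstl(fml("F [0, 5] ({A} > 0)"), tr),
               class = "stmc_trace_too_short")
  expect_error(evaluate_blstl(fml("X [3] ({A} > 0)"), tr),
               class = "stmc_trace_too_short")
  expect_error(evaluate_blstl(fml("d({A}) > 0"), tr, index = 3),
               class = "stmc_trace_too_short")
  # bounds are relative to the current state's time value
  tr2 <- as_trace(simple_exp(c(1, 5, 9), times = c(0L, 10L, 20L)))
  expect_true(evaluate_blstl(fml("F [10, 20] ({A} = 9)"), tr2))
  expect_false(evaluate_blstl(fml("F [11, 19] ({A} = 9)"), tr2))
})

test_that("missing variables and empty collections falsify the comparison", {
  st <- states_to_trace(list(
    state_with(0, regions = list(), vars = c(A = 1))))
  fml <- function(txt) parse_pblstl(paste0("P > 0.5 [ ", txt, " ]"))[[1]]$formula
  expect_false(evaluate_blstl(fml("{missing} > 0"), st))
  expect_false(evaluate_blstl(fml("{missing} <= 0"), st))
  expect_true(evaluate_blstl(fml("~({missing} > 0)"), st))
  expect_false(evaluate_blstl(fml("mean(regions, area) > 0"), st))
  expect_true(evaluate_blstl(fml("count(regions) = 0"), st))
  # NaN comparisons are false rather than errors
  expect_false(suppressWarnings(
    evaluate_blstl(fml("sqrt(subtract(0, {A})) > 0"), st)))
})

test_that("statistics follow their stated definitions", {
  ents <- list(entity_with(area = 2, density = 1),
               entity_with(area = 4, density = 2),
               entity_with(area = 9, density = 3))
  expect_equal(apply_statistic("count", ents), 3)
  expect_equal(apply_statistic("mean", ents[1:2], "area"), 3)
  expect_equal(apply_statistic("percentile", ents, "density", q = 50), 2)
  expect_equal(apply_statistic("percentile", ents, "density", q = 100), 3)
  expect_equal(apply_statistic("percentile", ents, "density", q = 0), 1)
  expect_equal(apply_statistic("stdev", ents, "area"), sd(c(2, 4, 9)))
  expect_equal(apply_statistic("stdev", ents[1], "area"), 0)
  expect_equal(apply_statistic("mode", list(entity_with(area = 2),
                                            entity_with(area = 2),
                                            entity_with(area = 5)), "area"),
               2)
  expect_equal(apply_statistic("covariance", ents, "area",
                               entities2 = ents, measure2 = "density"),
               cov(c(2, 4, 9), c(1, 2, 3)))
  expect_warning(
    v <- apply_statistic("covariance", ents, "area",
                         entities2 = ents[1:2], measure2 = "density"),
    "cardinality")
  expect_equal(v, cov(c(2, 4), c(1, 2)))
  expect_error(apply_statistic("mean", list(), "area"),
               class = "stmc_undefined")
  expect_equal(apply_statistic("count", list()), 0)
})

test_that("filters preserve order, are idempotent and reject non-measures", {
  ents <- list(entity_with(area = 5), entity_with(area = 12),
               entity_with(area = 20))
  cst <- parse_pblstl(
    "P > 0.5 [ count(filter(regions, area > 10)) > 0 ]"
  )[[1]]$formula$lhs$collection$filter
  kept <- filter_entities(ents, cst)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "area"), c(12, 20))
  expect_identical(filter_entities(kept, cst), kept)
  cst2 <- parse_pblstl(paste0(
    "P > 0.5 [ count(filter(regions, (area > 10) ^ ",
    "(circularMeasure >= 0.5))) > 0 ]"))[[1]]$formula$lhs$collection$filter
  both <- filter_entities(ents, cst2)
  expect_true(all(vapply(both, function(e)
    e$area > 10 && e$circularMeasure >= 0.5, logical(1))))
  true_cst <- parse_pblstl(
    "P > 0.5 [ count(filter(regions, area >= 0)) > 0 ]"
  )[[1]]$formula$lhs$collection$filter
  expect_identical(filter_entities(ents, true_cst), ents)
})

test_that("temporal dualities hold on random instances", {
  set.seed(77)
  for (i in 1:40) {
    states <- random_trace_states()
    tr <- states_to_trace(states)
    horizon <- max(vapply(states, function(s) s$time, numeric(1)))
    child <- random_formula_node(1, 0)
    a <- sample(0:2, 1); b <- a + sample(0:2, 1)
    if (b > horizon) next
    ev <- function(f) tryCatch(evaluate_blstl(f, tr),
                               stmc_trace_too_short = function(e) "short")
    f_not_f <- list(kind = "not",
                    child = list(kind = "F", a = a, b = b,
                                 child = child))
    g_not <- list(kind = "G", a = a, b = b,
                  child = list(kind = "not", child = child))
    expect_identical(ev(f_not_f), ev(g_not))
    # point windows: F and G coincide (exactly one state in the window)
    fa <- list(kind = "F", a = a, b = a, child = child)
    ga <- list(kind = "G", a = a, b = a, child = child)
    expect_identical(ev(fa), ev(ga))
    # purity: repeated evaluation is stable
    expect_identical(ev(f_not_f), ev(f_not_f))
  }
})
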