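test_that("limit points on the uniform closed form match brute-force oracles", {
  crv <- theoretical_abc(dist_spec("uniform"))

  pareto <- find_pareto_point(crv)
  expect_equal(pareto$effort, unif_pareto_effort, tolerance = 1e-5)

  be <- find_break_even(crv)
  expect_equal(be$effort, 0.5, tolerance = 1e-7)
  expect_true(is.na(be$degenerate))

  subm <- find_submarginal(crv, be)
  expect_equal(subm$effort, unif_submarginal_effort, tolerance = 1e-5)

  lim <- abc_limits(crv)
  expect_false(lim$swapped)
  expect_equal(lim$t_ab, unif_pareto_effort, tolerance = 1e-5)
  expect_equal(lim$t_bc, unif_submarginal_effort, tolerance = 1e-5)
  expect_equal(profit_gain(crv, lim$t_ab), 1.179509, tolerance = 1e-4)
  expect_equal(profit_gain(crv, lim$t_bc), 0.770917, tolerance = 1e-4)
})

test_that("the identity curve has its Pareto point at one half", {
  crv <- theoretical_abc(dist_spec("equality"))
  expect_equal(find_pareto_point(crv)$effort, 0.5, tolerance = 1e-6)
})

test_that("equality data is flagged degenerate with all gains at 1", {
  fit <- abc_analysis(rep(5, 5))
  expect_false(is.na(fit$limits$degenerate))
  expect_match(fit$limits$degenerate, "plateau|everywhere")
  expect_equal(profit_gain(fit$curve, seq(0, 1, by = 0.01)),
               rep(1, 101), tolerance = 1e-9)
  expect_equal(fit$limits$break_even$effort, 0)
})

test_that("break-even boundary conventions cover slopes that never cross 1", {
  # gain below 1 up to the last knot never happens for concave data through
  # (1,1); construct synthetic curves directly to exercise the conventions
  above <- structure(list(
    evaluate = function(p) p^0.99,
    derivative = function(p) pmax(0.99 * p^(-0.01), 1.0001),
    source = "synthetic"), class = "abc_curve")
  expect_equal(find_break_even(above)$effort, 1)
  expect_match(find_break_even(above)$degenerate, "above")

  below <- structure(list(
    evaluate = function(p) p,
    derivative = function(p) rep(0.9, length(p)),
    source = "synthetic"), class = "abc_curve")
  expect_equal(find_break_even(below)$effort, 0)
  expect_match(find_break_even(below)$degenerate, "below")
})

test_that("optimizers agree with an exhaustive grid scan", {
  cases <- expand.grid(n = c(8, 50, 1000), seed = 1:7)
  for (i in seq_len(nrow(cases))) {
    x <- random_positive(cases$n[i], 1000 + cases$seed[i] * 13 + cases$n[i])
    crv <- abc_curve(abc_points(x))

    f_par <- function(p) p^2 + (1 - crv$evaluate(p))^2
    expect_equal(find_pareto_point(crv)$effort, grid_argmin(f_par),
                 tolerance = 1e-4)

    bx <- find_break_even(crv)$effort
    f_sub <- function(p) (p - bx)^2 + (1 - crv$evaluate(p))^2
    expect_equal(find_submarginal(crv, find_break_even(crv))$effort,
                 grid_argmin(f_sub, lower = bx), tolerance = 1e-4)
  }
})

test_that("set A always has profit gain at least 1 and gains decrease toward C", {
  datasets <- c(
    lapply(1:6, function(s) random_positive(60, s)),
    list(pain_eigenvalues,
         c(10, rep(1, 99)), # forces the A/B role exchange
         abc_sample(dist_spec("lognormal", sdlog = 3), 400, seed = 5)$value)
  )
  for (x in datasets) {
    fit <- abc_analysis(x)
    lim <- fit$limits
    expect_gte(profit_gain(fit$curve, lim$t_ab), 1 - 1e-6)
    expect_lte(lim$t_ab, lim$t_bc)
    expect_lte(profit_gain(fit$curve, lim$t_bc),
               profit_gain(fit$curve, lim$t_ab) + 1e-9)
  }
})

test_that("the role exchange fires when the Pareto effort exceeds the BreakEven effort", {
  fit <- abc_analysis(c(10, rep(1, 99)))
  lim <- fit$limits
  expect_true(lim$swapped)
  expect_gt(lim$pareto$effort, lim$break_even$effort)
  expect_equal(lim$t_ab, lim$break_even$effort)
  # only the single dominant item is "important few"
  expect_equal(glance(fit)$n_a, 1)
})

test_that("set limits are scale invariant", {
  x <- random_positive(80, 42)
  base <- abc_limits(abc_curve(abc_points(x)))
  for (c_mult in c(0.01, 1000)) {
    scaled <- abc_limits(abc_curve(abc_points(c_mult * x)))
    expect_equal(scaled$t_ab, base$t_ab, tolerance = 1e-6)
    expect_equal(scaled$t_bc, base$t_bc, tolerance = 1e-6)
  }
})

test_that("partitions are complete, disjoint and ordered by value", {
  for (seed in 1:8) {
    n <- c(5, 23, 240)[(seed %% 3) + 1]
    fit <- abc_analysis(random_positive(n, seed * 3))
    part <- fit$partition
    expect_setequal(part$item, seq_len(n))
    expect_equal(sum(table(part$set)), n)
    a_vals <- part$value[part$set == "A"]
    b_vals <- part$value[part$set == "B"]
    c_vals <- part$value[part$set == "C"]
    if (length(a_vals) && length(b_vals)) expect_gte(min(a_vals), max(b_vals))
    if (length(b_vals) && length(c_vals)) expect_gte(min(b_vals), max(c_vals))
    if (length(a_vals) && length(c_vals)) expect_gte(min(a_vals), max(c_vals))
  }
})

test_that("a uniform sample of 1000 puts about 410 items in set A", {
  fit <- abc_analysis(abc_sample(dist_spec("uniform"), 1000, seed = 11))
  expect_equal(glance(fit)$n_a, 410, tolerance = 15 / 410)
})

test_that("repeated analysis of the same input is bit-identical", {
  x <- random_positive(50, 99)
  f1 <- abc_analysis(x)
  f2 <- abc_analysis(x)
  expect_identical(glance(f1), glance(f2))
  expect_identical(tidy(f1), tidy(f2))
})
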