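grid01 <- seq(0, 1, by = 0.01)

test_that("closed-form curves match their table values", {
  expect_equal(theoretical_abc(dist_spec("equality", c = 9))$evaluate(grid01),
               grid01)

  ex <- theoretical_abc(dist_spec("exponential", rate = 3))
  expect_equal(ex$evaluate(0.5), 0.5 - 0.5 * log(0.5), tolerance = 1e-12)
  # rate does not enter the curve
  ex2 <- theoretical_abc(dist_spec("exponential", rate = 0.01))
  expect_equal(ex$evaluate(grid01), ex2$evaluate(grid01), tolerance = 1e-12)

  pa <- theoretical_abc(dist_spec("pareto", alpha = 1.16))
  expect_equal(pa$evaluate(0.2), 0.2^(0.16 / 1.16), tolerance = 1e-12)
  expect_equal(pa$evaluate(0.2), 0.8009222, tolerance = 1e-6)
})

test_that("quantile-based curves match independent closed-form tail identities", {
  p <- c(1e-4, 0.01, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 1)

  ln <- theoretical_abc(dist_spec("lognormal", meanlog = 1, sdlog = 3))
  expect_equal(ln$evaluate(p), pnorm(3 + qnorm(p)), tolerance = 1e-6)

  ga <- theoretical_abc(dist_spec("gaussian", mean = 5, sd = 1))
  expect_equal(ga$evaluate(p), (5 * p + dnorm(qnorm(1 - p))) / 5,
               tolerance = 1e-6)

  ch <- theoretical_abc(dist_spec("chi_squared", df = 1))
  expect_equal(ch$evaluate(p), 1 - pchisq(qchisq(1 - p, 1), 3),
               tolerance = 1e-6)
})

test_that("lognormal curves depend only on the scale parameter", {
  a <- theoretical_abc(dist_spec("lognormal", meanlog = 0, sdlog = 3))
  b <- theoretical_abc(dist_spec("lognormal", meanlog = 4, sdlog = 3))
  expect_equal(a$evaluate(grid01), b$evaluate(grid01), tolerance = 1e-6)
})

test_that("gaussian curves near the origin demand truncation", {
  expect_error(theoretical_abc(dist_spec("gaussian", mean = 1, sd = 1)),
               "mean/sd")
  expect_s3_class(theoretical_abc(dist_spec("gaussian", mean = 4, sd = 1)),
                  "abc_curve")
})

test_that("parameter validation names the offending field", {
  expect_error(dist_spec("uniform", b = -1), "'b'")
  expect_error(dist_spec("pareto", alpha = 0.9), "'alpha'")
  expect_error(dist_spec("chi_squared", df = 0), "'df'")
  expect_error(dist_spec("exponential", lambda = 2), "unknown parameter")
  expect_error(dist_spec("weibull"), "arg")
})

test_that("ABC and Lorenz curves are duals of each other", {
  # closed-form pair for the exponential family
  ab <- theoretical_abc(dist_spec("exponential"))
  lo <- theoretical_lorenz(dist_spec("exponential"))
  expect_equal(ab$evaluate(grid01), 1 - lo$evaluate(1 - grid01),
               tolerance = 1e-12)

  # endpoints map to endpoints under both transforms
  for (spec in list(dist_spec("uniform"), dist_spec("pareto", alpha = 2))) {
    dual <- abc_from_lorenz(theoretical_lorenz(spec))
    expect_equal(dual$evaluate(c(0, 1)), c(0, 1))
    expect_equal(lorenz_from_abc(theoretical_abc(spec))$evaluate(c(0, 1)),
                 c(0, 1))
  }

  # round trip abc -> lorenz -> abc is the identity, also for splines
  curves <- list(theoretical_abc(dist_spec("uniform")),
                 theoretical_abc(dist_spec("pareto", alpha = 1.5)),
                 abc_curve(abc_points(pain_eigenvalues)))
  for (crv in curves) {
    back <- abc_from_lorenz(lorenz_from_abc(crv))
    expect_equal(back$evaluate(grid01), crv$evaluate(grid01),
                 tolerance = 1e-12)
  }
})

test_that("pareto shape calibration hits its target point exactly", {
  expect_equal(calibrate_pareto_alpha(0.25, 0.5), 2, tolerance = 1e-12)
  expect_equal(calibrate_pareto_alpha(0.2, 0.8), 1.160964, tolerance = 1e-6)

  for (tgt in list(c(0.2, 0.8), c(0.1, 0.66), c(0.4, 0.5))) {
    alpha <- calibrate_pareto_alpha(tgt[1], tgt[2])
    crv <- theoretical_abc(dist_spec("pareto", alpha = alpha))
    expect_equal(crv$evaluate(tgt[1]), tgt[2], tolerance = 1e-9)
  }

  expect_error(calibrate_pareto_alpha(0.8, 0.2), "exceed")
  expect_error(calibrate_pareto_alpha(0, 0.5), "inside")
  expect_error(calibrate_pareto_alpha(0.2, 1), "inside")
})

test_that("samples are reproducible, leave the RNG alone, and clip negatives", {
  spec <- dist_spec("uniform")
  s1 <- abc_sample(spec, 100, seed = 5)
  s2 <- abc_sample(spec, 100, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, abc_sample(spec, 100, seed = 6)))

  set.seed(314)
  state <- .Random.seed
  abc_sample(spec, 10, seed = 1)
  expect_identical(.Random.seed, state)

  expect_equal(abc_sample(dist_spec("equality", c = 2), 5, seed = 1)$value,
               rep(2, 5))

  m <- abc_sample(spec, 1e5, seed = 8)
  expect_lt(abs(mean(m$value) - 0.5), 0.01)

  expect_warning(
    clipped <- abc_sample(dist_spec("gaussian", mean = 0.5, sd = 1), 1000,
                          seed = 3),
    "clipped")
  expect_gt(attr(clipped, "clipped"), 0)
  expect_true(all(clipped$value >= 0))

  expect_error(abc_sample(spec, 0, seed = 1), "positive integer")
})

test_that("every theoretical curve is a valid ABC curve on a fine grid", {
  specs <- list(dist_spec("equality"), dist_spec("uniform", a = 2, b = 5),
                dist_spec("exponential"), dist_spec("pareto", alpha = 1.16),
                dist_spec("lognormal", sdlog = 3), dist_spec("gaussian"),
                dist_spec("chi_squared"))
  grid <- seq(0, 1, by = 1e-3)
  for (spec in specs) {
    crv <- theoretical_abc(spec)
    y <- crv$evaluate(grid)
    expect_equal(y[1], 0)
    expect_equal(y[length(y)], 1, tolerance = 1e-9)
    expect_true(all(y >= -1e-12 & y <= 1 + 1e-12))
    expect_true(all(diff(y) >= -1e-9))
    d <- crv$derivative(grid)
    expect_true(all(d >= 0))
    expect_true(all(diff(d) <= 1e-9))
  }
})

test_that("curve inequality ordering reflects distributional inequality", {
  grid <- seq(0, 1, by = 0.01)
  ln3 <- theoretical_abc(dist_spec("lognormal", sdlog = 3))$evaluate(grid)
  ex <- theoretical_abc(dist_spec("exponential"))$evaluate(grid)
  un <- theoretical_abc(dist_spec("uniform"))$evaluate(grid)
  ga <- theoretical_abc(dist_spec("gaussian", mean = 5, sd = 1))$evaluate(grid)

  expect_true(all(ln3 >= ex - 1e-9))
  expect_true(all(ex >= un - 1e-9))
  expect_true(all(un >= grid - 1e-9))
  # a narrow Gaussian sits between uniform-in-range and identity
  expect_true(all(ga <= un + 1e-9))
  expect_true(all(ga >= grid - 1e-9))
})
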