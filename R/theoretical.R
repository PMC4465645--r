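# Theoretical ABC and Lorenz curves for named distribution families,
# Pareto shape calibration, and seeded sampling for fixtures.

FAMILIES <- c("equality", "uniform", "exponential", "pareto",
              "lognormal", "gaussian", "chi_squared")

#' Specify a theoretical distribution
#'
#' A small container naming a distribution family and its parameters, used
#' to build closed-form or quantile-based ABC curves and to draw seeded
#' samples.
#'
#' Families and parameters (with defaults):
#' * `equality`: `c` (the common value, 1) — all items identical.
#' * `uniform`: `a` (lower end, 0) and `b` (range width, 1), i.e. uniform
#'   on `[a, a + b]`; `a >= 0`, `b > 0`.
#' * `exponential`: `rate` (1).
#' * `pareto`: shape `alpha` (1.16) and scale `x_min` (1); `alpha > 1` so
#'   the mean — and hence the ABC curve — exists.
#' * `lognormal`: `meanlog` (0) and `sdlog` (1).
#' * `gaussian`: `mean` (5) and `sd` (1). ABC curves need non-negative
#'   values; see [theoretical_abc()] for the support guard.
#' * `chi_squared`: `df` (1), `df >= 1`.
#'
#' @param family One of the family names above.
#' @param ... Named parameters overriding the defaults.
#' @return An object of class `abc_dist`.
#' @examples
#' dist_spec("pareto", alpha = 1.16)
#' @export
dist_spec <- function(family = FAMILIES, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    equality    = list(c = 1),
    uniform     = list(a = 0, b = 1),
    exponential = list(rate = 1),
    pareto      = list(alpha = 1.16, x_min = 1),
    lognormal   = list(meanlog = 0, sdlog = 1),
    gaussian    = list(mean = 5, sd = 1),
    chi_squared = list(df = 1)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter%s for family '%s': %s",
                  if (length(unknown) > 1) "s" else "", family,
                  paste(unknown, collapse = ", ")))
  }
  params <- utils::modifyList(defaults, override)
  check_pos <- function(name, strict = TRUE, min = 0) {
    v <- params[[name]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        (strict && v <= min) || (!strict && v < min)) {
      abort(sprintf("parameter '%s' of family '%s' must be %s %g",
                    name, family, if (strict) "greater than" else "at least",
                    min))
    }
  }
  switch(family,
    equality    = check_pos("c"),
    uniform     = { check_pos("a", strict = FALSE); check_pos("b") },
    exponential = check_pos("rate"),
    pareto      = { check_pos("alpha", min = 1); check_pos("x_min") },
    lognormal   = check_pos("sdlog"),
    gaussian    = check_pos("sd"),
    chi_squared = check_pos("df", strict = FALSE, min = 1)
  )
  structure(list(family = family, params = params), class = "abc_dist")
}

#' @export
print.abc_dist <- function(x, ...) {
  cat(sprintf("<abc_dist: %s(%s)>\n", x$family,
              paste(names(x$params), unlist(x$params),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Theoretical ABC curve of a distribution
#'
#' Builds the ABC curve `ABC(p)` = (mean of the top `p` tail) / (overall
#' mean) of a theoretical distribution. Closed forms are used where they
#' exist:
#' * equality: `ABC(p) = p`
#' * uniform on `[a, a+b]`: `((a+b) p - b p^2 / 2) / (a + b/2)`,
#'   i.e. `-p^2 + 2p` for `a = 0`
#' * exponential: `p - p log(p)` (independent of the rate)
#' * Pareto: `p^((alpha - 1)/alpha)` (independent of `x_min`)
#'
#' Lognormal, Gaussian and chi-squared curves are computed from the
#' definition by adaptive quadrature of the tail mass above the
#' `1 - p` quantile, divided by the mean; their profit gain is exact,
#' `dABC(p) = q(1 - p) / mean`. Lognormal curves depend only on `sdlog`,
#' exponential curves not on the rate.
#'
#' Gaussian curves are only meaningful when the negative tail is
#' negligible: the curve is computed on the positive part of the
#' distribution and requires `mean / sd >= 4` (negative mass below
#' `3.2e-5`); smaller ratios raise an error asking for explicit truncation
#' or shifting, since ABC curves are defined for non-negative values only.
#'
#' @param spec An [dist_spec()] object.
#' @return An `abc_curve` with source `"closed-form"` or
#'   `"numeric-quantile"`.
#' @examples
#' theoretical_abc(dist_spec("exponential"))$evaluate(0.5) # 0.5 - 0.5*log(0.5)
#' @export
theoretical_abc <- function(spec) {
  stopifnot(inherits(spec, "abc_dist"))
  p <- spec$params
  switch(spec$family,
    equality = {
      crv <- identity_curve()
      crv$source <- "closed-form"
      crv
    },
    uniform = uniform_abc_curve(p$a, p$b),
    exponential = new_abc_curve(
      evaluate = function(q) {
        check_unit_interval(q)
        ifelse(q == 0, 0, q - q * log(q))
      },
      derivative = function(q) {
        check_unit_interval(q)
        ifelse(q == 0, Inf, -log(q))
      },
      source = "closed-form"
    ),
    pareto = {
      ex <- (p$alpha - 1) / p$alpha
      new_abc_curve(
        evaluate = function(q) { check_unit_interval(q); q^ex },
        derivative = function(q) {
          check_unit_interval(q)
          ifelse(q == 0, Inf, ex * q^(ex - 1))
        },
        source = "closed-form"
      )
    },
    lognormal = quantile_abc_curve(
      qfun = function(u) qlnorm(u, p$meanlog, p$sdlog),
      dfun = function(x) dlnorm(x, p$meanlog, p$sdlog),
      mu = exp(p$meanlog + p$sdlog^2 / 2)
    ),
    gaussian = {
      if (p$mean / p$sd < 4) {
        abort(paste0(
          "gaussian ABC curve needs mean/sd >= 4 so the negative tail is ",
          "negligible; truncate or shift the distribution first"))
      }
      quantile_abc_curve(
        qfun = function(u) pmax(qnorm(u, p$mean, p$sd), 0),
        dfun = function(x) dnorm(x, p$mean, p$sd),
        mu = NULL # positive-part mean, computed by quadrature
      )
    },
    chi_squared = quantile_abc_curve(
      qfun = function(u) qchisq(u, p$df),
      dfun = function(x) dchisq(x, p$df),
      mu = p$df
    )
  )
}

# ABC curve from the quantile/density pair of a non-negative family:
#   ABC(p) = E[X ; X > q(1-p)] / E[X],
# the tail mass integrated by adaptive quadrature on the log scale
# (x = e^w tames the dynamic range of heavy tails such as lognormal s = 3),
# and dABC(p) = q(1-p) / E[X] exactly (chain rule on the tail integral).
quantile_abc_curve <- function(qfun, dfun, mu = NULL) {
  g <- function(w) {
    v <- exp(2 * w) * dfun(exp(w))
    v[!is.finite(v)] <- 0
    v
  }
  log_med <- log(qfun(0.5))
  quad <- function(lo, hi) {
    integrate(g, lo, hi, rel.tol = 1e-10, subdivisions = 500L)$value
  }
  tail_mass <- function(cut) {
    if (!is.finite(cut) && cut > 0) return(0)
    lo <- if (cut <= 0) -60 else log(cut) # e^-60: below any relevant mass
    if (lo < log_med) {
      # split at the median so the quadrature brackets the density bump
      quad(lo, log_med) + quad(log_med, Inf)
    } else {
      quad(lo, Inf)
    }
  }
  if (is.null(mu)) mu <- tail_mass(0)
  evaluate <- function(p) {
    check_unit_interval(p)
    vapply(p, function(pp) {
      if (pp <= 0) return(0)
      if (pp >= 1) return(1)
      min(max(tail_mass(qfun(1 - pp)) / mu, 0), 1)
    }, numeric(1))
  }
  derivative <- function(p) {
    check_unit_interval(p)
    pmax(qfun(1 - p), 0) / mu
  }
  new_abc_curve(evaluate, derivative, source = "numeric-quantile")
}

#' Lorenz curves and the ABC-Lorenz duality
#'
#' The ABC curve and the Lorenz curve of a distribution are mirror images:
#' `ABC(p) = 1 - L(1 - p)` and `L(p) = 1 - ABC(1 - p)`. A Lorenz curve
#' reads "the poorest fraction p holds L(p) of the total"; the ABC curve
#' reads "the top fraction p holds ABC(p)". The two conversions are exact
#' pointwise transforms and are mutual inverses.
#'
#' `lorenz_curve()` wraps an evaluator (and optionally its derivative) as a
#' `lorenz_curve` object; `theoretical_lorenz()` gives the closed forms for
#' the families that have one (`p` for equality, `p + (1-p) log(1-p)` for
#' exponential, `1 - (1-p)^((alpha-1)/alpha)` for Pareto,
#' `(b p^2 / 2 + a p)/(a + b/2)` for uniform) and falls back to the dual of
#' the numeric ABC curve otherwise.
#'
#' @param evaluate Function mapping `p` in `[0,1]` to `L(p)`.
#' @param derivative Optional derivative of `evaluate`.
#' @param spec An [dist_spec()] object.
#' @param l A `lorenz_curve`.
#' @param curve An `abc_curve`.
#' @return `lorenz_curve()` and `lorenz_from_abc()` return a
#'   `lorenz_curve`; `abc_from_lorenz()` returns an `abc_curve`.
#' @name lorenz
NULL

#' @rdname lorenz
#' @export
lorenz_curve <- function(evaluate, derivative = NULL) {
  structure(list(evaluate = evaluate, derivative = derivative),
            class = "lorenz_curve")
}

#' @rdname lorenz
#' @export
theoretical_lorenz <- function(spec) {
  stopifnot(inherits(spec, "abc_dist"))
  pars <- spec$params
  switch(spec$family,
    equality = lorenz_curve(function(p) { check_unit_interval(p); p },
                            function(p) rep(1, length(p))),
    exponential = lorenz_curve(
      function(p) {
        check_unit_interval(p)
        ifelse(p == 1, 1, p + (1 - p) * log1p(-p))
      },
      function(p) ifelse(p == 1, Inf, -log1p(-p))
    ),
    pareto = {
      ex <- (pars$alpha - 1) / pars$alpha
      lorenz_curve(function(p) { check_unit_interval(p); 1 - (1 - p)^ex })
    },
    uniform = lorenz_curve(
      function(p) {
        check_unit_interval(p)
        (0.5 * pars$b * p^2 + pars$a * p) / (pars$a + 0.5 * pars$b)
      },
      function(p) (pars$b * p + pars$a) / (pars$a + 0.5 * pars$b)
    ),
    lorenz_from_abc(theoretical_abc(spec))
  )
}

#' @rdname lorenz
#' @export
abc_from_lorenz <- function(l) {
  stopifnot(inherits(l, "lorenz_curve"))
  deriv <- if (!is.null(l$derivative)) {
    function(p) { check_unit_interval(p); l$derivative(1 - p) }
  } else {
    function(p) {
      check_unit_interval(p)
      h <- 1e-6
      lo <- pmax(p - h, 0); hi <- pmin(p + h, 1)
      ((1 - l$evaluate(1 - hi)) - (1 - l$evaluate(1 - lo))) / (hi - lo)
    }
  }
  new_abc_curve(
    evaluate = function(p) { check_unit_interval(p); 1 - l$evaluate(1 - p) },
    derivative = deriv,
    source = "lorenz-dual"
  )
}

#' @rdname lorenz
#' @export
lorenz_from_abc <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  lorenz_curve(
    evaluate = function(p) { check_unit_interval(p); 1 - curve$evaluate(1 - p) },
    derivative = function(p) { check_unit_interval(p); curve$derivative(1 - p) }
  )
}

#' Calibrate the Pareto shape so the ABC curve passes through a point
#'
#' For the Pareto family the ABC curve is `ABC(p) = p^((alpha-1)/alpha)`;
#' given a target `(effort, yield)` point in the open unit square with
#' `yield > effort`, the unique shape parameter is
#' `alpha = 1 / (1 - log(yield) / log(effort))`. The Juran "80/20" point
#' `(0.2, 0.8)` gives `alpha` close to 1.16.
#'
#' @param target_effort,target_yield The point the curve must pass through;
#'   both in `(0, 1)` with `target_yield > target_effort`.
#' @return The calibrated shape parameter `alpha`.
#' @examples
#' calibrate_pareto_alpha(0.2, 0.8) # ~1.16
#' @export
calibrate_pareto_alpha <- function(target_effort, target_yield) {
  if (!is.numeric(target_effort) || !is.numeric(target_yield) ||
      target_effort <= 0 || target_effort >= 1 ||
      target_yield <= 0 || target_yield >= 1) {
    abort("target_effort and target_yield must lie strictly inside (0, 1)")
  }
  if (target_yield <= target_effort) {
    abort("target_yield must exceed target_effort (ABC curves lie above the diagonal)")
  }
  1 / (1 - log(target_yield) / log(target_effort))
}

#' Draw a reproducible sample from a distribution spec
#'
#' Samples `n` values with a fixed seed, leaving the caller's RNG state
#' untouched. Gaussian draws below zero are clipped to zero (ABC analysis is
#' defined for non-negative values); the number of clipped draws is stored
#' in the `clipped` attribute and reported as a warning when positive.
#'
#' @param spec An [dist_spec()] object.
#' @param n Sample size, `n >= 1`.
#' @param seed Integer seed fixing the stream.
#' @return A tibble with column `value` and attribute `clipped`.
#' @examples
#' abc_sample(dist_spec("uniform"), n = 5, seed = 1)
#' @export
abc_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "abc_dist"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("n must be a positive integer")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  pars <- spec$params
  x <- switch(spec$family,
    equality    = rep(pars$c, n),
    uniform     = runif(n, pars$a, pars$a + pars$b),
    exponential = rexp(n, pars$rate),
    pareto      = pars$x_min * runif(n)^(-1 / pars$alpha),
    lognormal   = rlnorm(n, pars$meanlog, pars$sdlog),
    gaussian    = rnorm(n, pars$mean, pars$sd),
    chi_squared = rchisq(n, pars$df)
  )
  clipped <- sum(x < 0)
  if (clipped > 0) {
    warn(sprintf("clipped %d negative draw%s to zero", clipped,
                 if (clipped == 1) "" else "s"))
    x <- pmax(x, 0)
  }
  out <- tibble::tibble(value = x)
  attr(out, "clipped") <- clipped
  out
}
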