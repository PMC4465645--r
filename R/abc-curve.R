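# Continuous ABC curves: construction, evaluation, reference curves.
#
# An ABC curve is a non-decreasing concave function through (0,0) and (1,1)
# in the unit square; its slope dY/dE is the "profit gain". Empirical curves
# are interpolated from the discrete (E_i, Y_i) points with a
# shape-preserving piecewise-quadratic (C1) spline; theoretical curves carry
# closed-form or quadrature-based evaluators.

new_abc_curve <- function(evaluate, derivative, source,
                          collapsed = FALSE, extra = list()) {
  structure(
    list(evaluate = evaluate, derivative = derivative, source = source,
         collapsed = collapsed, extra = extra),
    class = "abc_curve"
  )
}

#' Fit a continuous ABC curve through discrete effort-yield points
#'
#' Interpolates the points `(0,0), (E_1,Y_1), ..., (E_n,Y_n) = (1,1)` with a
#' C1 piecewise-quadratic spline whose derivative is piecewise linear. Knot
#' slopes are taken as averages of neighbouring secant slopes; where a single
#' quadratic piece cannot match both endpoint slopes, an interior knot is
#' inserted (Schumaker-style). Because the yield increments of decreasingly
#' sorted non-negative data are themselves non-increasing, the construction
#' preserves monotonicity and concavity exactly: the spline's derivative is
#' non-negative and non-increasing on all of `[0, 1]`, with no overshoot.
#' Segments with equal neighbouring secants degenerate to straight lines, so
#' equality-distributed data reproduces the diagonal exactly.
#'
#' @param points An [abc_points] tibble (or any data frame with `effort` and
#'   `yield` columns covering ranks `1..n`), `n >= 3`.
#'
#' @return An object of class `abc_curve`: a list with functions
#'   `evaluate(p)` and `derivative(p)` defined on `[0, 1]`, plus a `source`
#'   tag (`"empirical-spline"` here).
#'
#' @examples
#' crv <- abc_curve(abc_points(c(5, 3, 2, 1, 1)))
#' crv$evaluate(c(0, 0.5, 1))
#' @export
abc_curve <- function(points) {
  if (!all(c("effort", "yield") %in% names(points))) {
    abort("`points` must have effort and yield columns (see abc_points())")
  }
  if (nrow(points) < 3) {
    abort("quadratic interpolation is undefined for fewer than 3 points; supply n >= 3 values")
  }
  px <- c(0, points$effort)
  py <- c(0, points$yield)
  sp <- shape_spline(px, py)
  new_abc_curve(
    evaluate   = function(p) spline_eval(sp, p),
    derivative = function(p) spline_deriv(sp, p),
    source     = "empirical-spline",
    extra      = list(spline = sp, n = nrow(points))
  )
}

# Shape-preserving quadratic spline for concave non-decreasing data.
# Each piece is y0 + d0*(t - t0) + c*(t - t0)^2; the derivative runs linearly
# from one knot slope to the next. For intervals where the endpoint slopes
# do not average to the secant, one extra knot is inserted so that the
# derivative is constant on part of the interval — this keeps the derivative
# monotone (concavity) while matching values and slopes exactly.
shape_spline <- function(px, py) {
  m <- length(px)
  h <- diff(px)
  s <- diff(py) / h # secant slopes; non-increasing for ABC data
  if (m == 2) {
    d <- c(s, s)
  } else {
    d <- numeric(m)
    d[2:(m - 1)] <- (s[-length(s)] + s[-1]) / 2
    d[1] <- (3 * s[1] - d[2]) / 2
    d[m] <- max(0, (3 * s[length(s)] - d[m - 1]) / 2)
  }
  eps <- 1e-12
  np <- 2L * (m - 1L) # at most two pieces per interval
  t0 <- y0 <- d0 <- cc <- numeric(np)
  k <- 0L
  put <- function(t, y, d, c2) {
    k <<- k + 1L
    t0[k] <<- t; y0[k] <<- y; d0[k] <<- d; cc[k] <<- c2
  }
  for (i in seq_len(m - 1)) {
    dl <- d[i]; dr <- d[i + 1]; hi <- h[i]; si <- s[i]
    if (abs(dl + dr - 2 * si) <= eps * (1 + abs(si)) || abs(dl - dr) <= eps) {
      # single quadratic (degenerates to a line when dl == dr == si)
      put(px[i], py[i], dl, (dr - dl) / (2 * hi))
    } else if (dl + dr > 2 * si) {
      # slope surplus: quadratic down to dr, then linear at dr
      a <- 2 * hi * (si - dr) / (dl - dr)
      a <- min(max(a, 0), hi)
      put(px[i], py[i], dl, if (a > 0) (dr - dl) / (2 * a) else 0)
      put(px[i] + a, py[i] + a * (dl + dr) / 2, dr, 0)
    } else {
      # slope deficit: linear at dl, then quadratic down to dr
      a <- hi * (2 * si - dl - dr) / (dl - dr)
      a <- min(max(a, 0), hi)
      put(px[i], py[i], dl, 0)
      put(px[i] + a, py[i] + a * dl, dl,
          if (hi - a > 0) (dr - dl) / (2 * (hi - a)) else 0)
    }
  }
  list(t0 = t0[seq_len(k)], y0 = y0[seq_len(k)], d0 = d0[seq_len(k)],
       cc = cc[seq_len(k)], upper = px[m], y_upper = py[m])
}

spline_piece <- function(sp, p) {
  pmin(pmax(findInterval(p, sp$t0, rightmost.closed = FALSE), 1L),
       length(sp$t0))
}

spline_eval <- function(sp, p) {
  check_unit_interval(p)
  i <- spline_piece(sp, p)
  t <- p - sp$t0[i]
  y <- sp$y0[i] + sp$d0[i] * t + sp$cc[i] * t * t
  y[p >= sp$upper] <- sp$y_upper
  y[p <= 0] <- 0
  pmin(pmax(y, 0), 1)
}

spline_deriv <- function(sp, p) {
  check_unit_interval(p)
  i <- spline_piece(sp, p)
  pmax(sp$d0[i] + 2 * sp$cc[i] * (p - sp$t0[i]), 0)
}

check_unit_interval <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("effort fraction p must lie in [0, 1]")
  }
  invisible(p)
}

#' Profit gain (slope) of an ABC curve
#'
#' The profit gain is the first derivative dY/dE of the ABC curve: the rate
#' at which yield is gained per unit of additional effort at effort fraction
#' `p`. Values above 1 mean over-proportional return (candidate set A),
#' values below 1 under-proportional return (candidate set C).
#'
#' @param curve An `abc_curve`.
#' @param p Effort fraction(s) in `[0, 1]`.
#' @return The non-negative slope(s) at `p`.
#' @examples
#' u <- theoretical_abc(dist_spec("uniform"))
#' profit_gain(u, 0) # uniform data starts at gain 2
#' @export
profit_gain <- function(curve, p) {
  stopifnot(inherits(curve, "abc_curve"))
  check_unit_interval(p)
  curve$derivative(p)
}

#' Reference curves for judging the inequality of a data set
#'
#' Returns the two comparison curves drawn in ABC plots: the identity curve
#' `ABC(p) = p` (all items equal) and the closed-form ABC curve of the
#' uniform distribution over the observed data range
#' `[min(x), max(x)]`. Data whose curve lies above the uniform reference is
#' more right-skewed (more unequal) than uniform noise over the same range.
#'
#' @inheritParams abc_points
#' @return A list with `abc_curve` elements `identity` and
#'   `uniform_in_range`. When all values are equal the uniform reference
#'   collapses to the identity curve; it is still returned, with its
#'   `collapsed` field set to `TRUE`.
#' @export
reference_curves <- function(data, value = NULL) {
  x <- if (is.data.frame(data)) pull_values(data, {{ value }}) else data
  x <- validate_values(x)
  a <- min(x)
  b <- max(x) - min(x)
  identity_crv <- identity_curve()
  if (b <= 0) {
    uni <- identity_curve()
    uni$collapsed <- TRUE
    uni$source <- "reference"
    return(list(identity = identity_crv, uniform_in_range = uni))
  }
  list(identity = identity_crv,
       uniform_in_range = uniform_abc_curve(a, b))
}

identity_curve <- function() {
  new_abc_curve(
    evaluate   = function(p) { check_unit_interval(p); p },
    derivative = function(p) { check_unit_interval(p); rep(1, length(p)) },
    source     = "reference"
  )
}

# Closed-form ABC curve of Uniform[a, a+b]:
#   ABC(p) = ((a+b) p - b p^2 / 2) / (a + b/2),
# which reduces to -p^2 + 2p for a = 0.
uniform_abc_curve <- function(a, b) {
  denom <- a + b / 2
  new_abc_curve(
    evaluate = function(p) {
      check_unit_interval(p)
      ((a + b) * p - 0.5 * b * p^2) / denom
    },
    derivative = function(p) {
      check_unit_interval(p)
      ((a + b) - b * p) / denom
    },
    source = "closed-form",
    extra = list(family = "uniform", a = a, b = b)
  )
}

#' @export
print.abc_curve <- function(x, ...) {
  cat(sprintf("<abc_curve: %s%s>\n", x$source,
              if (isTRUE(x$collapsed)) ", collapsed to identity" else ""))
  invisible(x)
}
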