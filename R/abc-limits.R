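# Set limits on an ABC curve: the Pareto, BreakEven and SubMarginal points,
# the derived thresholds t_AB and t_BC, and the A/B/C partition.
#
# The rejected alternative for the A/B limit is the Manhattan distance
# distM = E + (1 - ABC(E)): its minimum sits exactly where the profit gain
# equals 1, so set A would not have gain > 1. It is therefore not exposed;
# only the Euclidean distance distE = sqrt(E^2 + (1 - ABC(E))^2) is used.

curve_point <- function(curve, effort, point, degenerate = NA_character_) {
  tibble::tibble(
    point  = point,
    effort = effort,
    yield  = curve$evaluate(effort),
    gain   = curve$derivative(effort),
    degenerate = degenerate
  )
}

# Deterministic minimiser: dense grid scan followed by Brent refinement in
# the bracketing interval. No randomness, so results are reproducible
# without seeds.
minimize_on_curve <- function(f, lower = 0, upper = 1,
                              step = 1e-4, tol = 1e-9) {
  if (upper - lower <= tol) {
    return(lower)
  }
  grid <- seq(lower, upper, by = step)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  fv <- f(grid)
  i <- which.min(fv)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(function(p) f(p), interval = c(lo, hi), tol = tol)
  if (opt$objective <= fv[i]) opt$minimum else grid[i]
}

#' Pareto point: closest approach to the ideal of zero effort, full yield
#'
#' Locates the point on the ABC curve with the smallest Euclidean distance
#' to the ideal point (0, 1), i.e. the minimiser of
#' `sqrt(p^2 + (1 - ABC(p))^2)` over `p` in `[0, 1]`. Its effort coordinate
#' is one of the two candidates for the set-A limit.
#'
#' @param curve An `abc_curve`.
#' @return A one-row tibble with columns `point`, `effort`, `yield`, `gain`
#'   and `degenerate`.
#' @examples
#' find_pareto_point(theoretical_abc(dist_spec("uniform")))$effort # ~0.41
#' @export
find_pareto_point <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  f <- function(p) p^2 + (1 - curve$evaluate(p))^2
  curve_point(curve, minimize_on_curve(f), "pareto")
}

#' BreakEven point: where the profit gain crosses 1
#'
#' Locates the effort at which the slope of the ABC curve equals 1, i.e.
#' where one extra unit of effort returns exactly one unit of yield. The
#' derivative of an ABC curve is non-increasing, so the crossing is found by
#' bisection. Degenerate cases are flagged rather than fatal: if the gain
#' exceeds 1 everywhere the effort is 1; if it is below 1 everywhere the
#' effort is 0; if the gain sits at 1 on a plateau (equality-like data) the
#' plateau's left endpoint is returned.
#'
#' @inheritParams find_pareto_point
#' @return A one-row tibble as in [find_pareto_point()]; `degenerate` is
#'   `NA` for a clean crossing and a short reason otherwise.
#' @export
find_break_even <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  tol <- 1e-6
  dv <- function(p) curve$derivative(p)
  if (dv(1) > 1 + tol) {
    return(curve_point(curve, 1, "break_even", "gain above 1 everywhere"))
  }
  if (dv(0) < 1 - tol) {
    return(curve_point(curve, 0, "break_even", "gain below 1 everywhere"))
  }
  # leftmost p with gain <= 1 (plateaus at 1 resolve to their left end)
  lo <- 0; hi <- 1
  if (dv(0) <= 1) {
    hi <- 0
  } else {
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (dv(mid) <= 1) hi <- mid else lo <- mid
    }
  }
  # a spline knot can carry a downward jump in the gain; if the bisection
  # lands just right of a jump across 1, report the left side so that set A
  # keeps gain >= 1 up to its boundary
  p_be <- if (dv(hi) >= 1 - tol) hi else lo
  plateau <- abs(dv(min(p_be + 1e-3, 1)) - 1) <= tol
  curve_point(curve, p_be, "break_even",
              if (plateau) "gain plateau at 1" else NA_character_)
}

#' SubMarginal point: closest approach to full yield at BreakEven effort
#'
#' Given the BreakEven point `(Bx, By)`, the ideal situation is that all
#' yield were already gained at that effort, i.e. the point `(Bx, 1)`. The
#' SubMarginal point is the point on the ABC curve at minimum Euclidean
#' distance from `(Bx, 1)`, searched over `p` in `[Bx, 1]`. Everything to
#' its right has a profit gain substantially below 1 and belongs to set C.
#'
#' @inheritParams find_pareto_point
#' @param break_even A point tibble from [find_break_even()] computed on the
#'   same curve (after any role exchange with the Pareto point).
#' @return A one-row tibble as in [find_pareto_point()].
#' @export
find_submarginal <- function(curve, break_even) {
  stopifnot(inherits(curve, "abc_curve"))
  bx <- break_even$effort[1]
  f <- function(p) (p - bx)^2 + (1 - curve$evaluate(p))^2
  curve_point(curve, minimize_on_curve(f, lower = bx, upper = 1),
              "submarginal")
}

#' Set limits of an ABC analysis
#'
#' Computes the three characteristic points of the curve and derives the set
#' limits: `t_AB = min(Ax, Bx)` where `Ax` is the Pareto effort and `Bx` the
#' BreakEven effort, and `t_BC = Cx`, the SubMarginal effort. Usually
#' `Ax <= Bx`; when instead `Ax > Bx` the two points exchange their roles
#' (`swapped = TRUE`), which guarantees that the profit gain over set A is
#' at least 1 for every distribution. After an exchange the SubMarginal
#' search is anchored at the role-exchanged BreakEven effort `max(Ax, Bx)`,
#' preserving `t_AB <= t_BC`.
#'
#' @inheritParams find_pareto_point
#' @return An object of class `abc_limits`: a list with the three point
#'   rows (`pareto`, `break_even`, `submarginal`), the thresholds `t_ab`
#'   and `t_bc`, and the flags `swapped` and `degenerate`.
#' @examples
#' lim <- abc_limits(theoretical_abc(dist_spec("uniform")))
#' c(lim$t_ab, lim$t_bc)
#' @export
abc_limits <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  pareto <- find_pareto_point(curve)
  breake <- find_break_even(curve)
  swapped <- pareto$effort > breake$effort + 1e-9
  anchor <- if (swapped) pareto else breake
  subm <- find_submarginal(curve, anchor)
  t_ab <- min(pareto$effort, breake$effort)
  t_bc <- max(subm$effort, t_ab)
  structure(
    list(pareto = pareto, break_even = breake, submarginal = subm,
         t_ab = t_ab, t_bc = t_bc, swapped = swapped,
         degenerate = breake$degenerate[1]),
    class = "abc_limits"
  )
}

#' @export
print.abc_limits <- function(x, ...) {
  cat(sprintf(
    "<abc_limits: t_AB = %.4f, t_BC = %.4f%s%s>\n", x$t_ab, x$t_bc,
    if (x$swapped) ", A/B roles exchanged" else "",
    if (!is.na(x$degenerate)) paste0(", ", x$degenerate) else ""
  ))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.abc_limits <- function(x, ...) {
  dplyr::bind_rows(x$pareto, x$break_even, x$submarginal)
}

#' Partition items into sets A, B and C
#'
#' Assigns every item to exactly one set by rank on the decreasingly sorted
#' values. The item of rank `i` occupies the effort span
#' `((i-1)/n, i/n]`; it is assigned to the set in which the majority of
#' that span lies, i.e. rank `i` belongs to set A iff its span midpoint
#' `(i - 1/2)/n` is at most `t_AB`, to set C iff the midpoint exceeds
#' `t_BC`, and to set B otherwise (a `1e-9` guard absorbs floating-point
#' representation of the thresholds). Membership is decided by rank, never
#' by value, so tied values may straddle a boundary by their stable input
#' order but never share a rank.
#'
#' @param points An [abc_points] tibble.
#' @param limits An [abc_limits] object computed from the curve of the same
#'   data.
#' @return A tibble of class `abc_partition`: the `points` columns plus a
#'   `set` factor with levels A, B, C.
#' @export
abc_partition <- function(points, limits) {
  stopifnot(inherits(limits, "abc_limits"))
  n <- nrow(points)
  # rank i is left of a threshold t when its span midpoint (i - 0.5)/n <= t
  n_a <- floor(n * limits$t_ab + 0.5 + 1e-9)
  n_ab <- floor(n * limits$t_bc + 0.5 + 1e-9)
  set <- factor(
    dplyr::case_when(points$rank <= n_a ~ "A",
                     points$rank > n_ab ~ "C",
                     .default = "B"),
    levels = c("A", "B", "C")
  )
  out <- dplyr::mutate(points, set = set)
  class(out) <- c("abc_partition", setdiff(class(points), "abc_points"))
  out
}

#' Computed ABC analysis of non-negative data
#'
#' One-call pipeline: discrete effort-yield points, spline-interpolated ABC
#' curve, set limits with the swap rule, and the A/B/C partition. Set A
#' collects the "important few" (profit gain at least 1 throughout), set C
#' the "trivial many", set B the items in between with gains around 1.
#'
#' @inheritParams abc_points
#' @return An object of class `abc_analysis` bundling `points`, `curve`,
#'   `limits` and `partition`. Use [tidy()] for the per-item table,
#'   [glance()] for a one-row summary and [autoplot()] for the ABC plot.
#' @examples
#' fit <- abc_analysis(c(3.834, 1.142, 1.061, 0.740, 0.491, 0.432, 0.208, 0.092))
#' glance(fit)
#' @export
abc_analysis <- function(data, ...) UseMethod("abc_analysis")

#' @rdname abc_analysis
#' @export
abc_analysis.data.frame <- function(data, value = NULL, ...) {
  abc_analysis(pull_values(data, {{ value }}), ...)
}

#' @rdname abc_analysis
#' @export
abc_analysis.numeric <- function(data, ...) {
  points <- abc_points(data)
  curve <- abc_curve(points)
  limits <- abc_limits(curve)
  partition <- abc_partition(points, limits)
  structure(
    list(points = points, curve = curve, limits = limits,
         partition = partition),
    class = "abc_analysis"
  )
}

#' @export
print.abc_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<abc_analysis: n = %d | A: %d (%.1f%% yield) B: %d (%.1f%%) C: %d (%.1f%%) | t_AB = %.4f t_BC = %.4f>\n",
    g$n, g$n_a, 100 * g$yield_a, g$n_b, 100 * g$yield_b,
    g$n_c, 100 * g$yield_c, g$t_ab, g$t_bc
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.abc_analysis <- function(x, ...) {
  tibble::as_tibble(x$partition)
}

#' @exportS3Method generics::glance
glance.abc_analysis <- function(x, ...) {
  part <- x$partition
  total <- attr(x$points, "total")
  share <- function(s) sum(part$value[part$set == s]) / total
  tibble::tibble(
    n = nrow(part),
    t_ab = x$limits$t_ab,
    t_bc = x$limits$t_bc,
    swapped = x$limits$swapped,
    degenerate = x$limits$degenerate,
    n_a = sum(part$set == "A"),
    n_b = sum(part$set == "B"),
    n_c = sum(part$set == "C"),
    yield_a = share("A"),
    yield_b = share("B"),
    yield_c = share("C"),
    pareto_effort = x$limits$pareto$effort,
    break_even_effort = x$limits$break_even$effort,
    submarginal_effort = x$limits$submarginal$effort
  )
}
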