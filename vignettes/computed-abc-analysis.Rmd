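---
title: "Computed ABC analysis: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computed ABC analysis: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcsets)
```

## The model

ABC analysis partitions `n` non-negative values — eigenvalues, effect
sizes, abundances, counts — into set A (the "important few"), set B
(items whose yield is roughly proportional to their cost) and set C (the
"trivial many"). The object everything is computed on is the **ABC
curve**: sort the values decreasingly, and for each rank `i` plot the
yield `Y_i` (cumulative share of the total carried by the `i` largest
values) against the effort `E_i = i/n` (share of items considered).

Structural facts the package relies on, and asserts as test invariants:

* the curve runs from (0, 0) to (1, 1), is non-decreasing and concave,
  and lies on or above the diagonal;
* it is invariant under scaling of the data (`c * x` gives the same curve)
  but not under shifts — adding a constant flattens it toward the
  diagonal, which is why the only standardization the package offers is
  division by the standard deviation (`scale_to_unit_variance()`), never
  centering;
* it is the mirror image of the Lorenz curve, `ABC(p) = 1 - L(1 - p)`:
  the Lorenz curve accumulates from the poorest items, the ABC curve from
  the richest.

The slope `dABC = dY/dE` is the **profit gain**: the marginal yield per
marginal effort, non-increasing by concavity. The set limits are defined
through three points on the curve:

* **Pareto point** `A`: the argmin of `sqrt(p^2 + (1 - ABC(p))^2)`, the
  closest approach to the ideal (0, 1) of zero effort and full yield.
  The Manhattan-distance alternative `p + (1 - ABC(p))` was considered
  and rejected in the field because its minimum sits exactly at profit
  gain 1, which would leave set A without over-proportional returns; the
  Euclidean distance puts the boundary at gain ≈ 1.18 on the uniform
  reference curve.
* **BreakEven point** `B`: where the profit gain crosses 1.
* **SubMarginal point** `C`: the argmin over `p >= Bx` of the distance to
  `(Bx, 1)` — the closest approach to "all yield already gained at
  break-even effort".

`t_AB = min(Ax, Bx)` and `t_BC = Cx`. Usually `Ax <= Bx`; when a curve
has `Ax > Bx` the two points exchange roles (`swapped = TRUE`), which is
exactly the condition needed so that the gain over all of set A stays
at least 1. After an exchange the SubMarginal search is anchored at
`max(Ax, Bx)`; this preserves `t_AB <= t_BC` and the monotone ordering of
gains across the three sets.

On the closed-form uniform curve `ABC(p) = -p^2 + 2p` these definitions
have exact answers, which the tests and the acceptance script recompute:
the Pareto effort is the root of `2p = 4(1 - p)^3` (0.41025), the
BreakEven effort is 0.5, and the SubMarginal effort is the root of
`2(p - 1/2) = 4(1 - p)^3` (0.61454). The resulting set-B gain range is
[0.771, 1.180]. Rounded two-decimal versions of these numbers circulate
in the literature (a set-C share of "38%", a lower gain of "0.78"); the
package always reports the values its own optimisation produces.

## Interpolation: a shape-preserving quadratic spline

With discrete data the curve between the points `(E_i, Y_i)` must be
interpolated, and a careless interpolant can destroy the very properties
(monotonicity, concavity) the limit definitions depend on. The package
uses a C1 piecewise-quadratic spline with Schumaker-style knot insertion:

* knot slopes are means of adjacent secant slopes (with one-sided
  extrapolation at the ends, the last slope clamped at 0);
* on each interval, if one quadratic cannot match both endpoint slopes
  and the secant, an interior knot is inserted so the derivative is
  constant on part of the interval;
* because the yield increments of decreasingly sorted non-negative data
  are non-increasing, the construction is automatically monotone and
  concave — no post-hoc clipping is needed, and intervals with equal
  neighbouring secants degenerate to straight lines, so equality data
  reproduces the diagonal exactly.

In the extreme case where a secant equals the right knot slope but not
the left one (e.g. one dominant value followed by a run of ties) the
inserted interval has zero width and the derivative jumps downward at the
knot. The BreakEven search accounts for this: if the gain jumps across 1
at a knot, the knot itself (the left side of the jump) is reported, so
set A never contains efforts with gain below 1.

## Locating the limit points

The two distance minimisations use a deterministic dense grid (step
1e-4) followed by Brent refinement in the bracketing interval (tolerance
1e-9); there is no stochastic search, so identical inputs give
bit-identical limits. The BreakEven point is found by bisection on the
non-increasing derivative to 1e-9. Degenerate slopes are flagged, not
fatal: gain above 1 everywhere returns effort 1, below 1 everywhere
returns 0, and a plateau at exactly 1 (equality-like data) returns the
plateau's left endpoint with a `degenerate` note. Tests verify the
optimisers against exhaustive grid scans at step 1e-5 for sample sizes 8,
50 and 1000.

## From thresholds to set membership

The thresholds live on the continuous effort axis; items live on ranks.
The item of rank `i` occupies the effort span `((i-1)/n, i/n]`, and a
threshold can fall anywhere inside a span. The package assigns each item
to the side of the threshold holding the majority of its span: rank `i`
is left of `t` iff its midpoint `(i - 1/2)/n <= t`. The alternative
convention — comparing the span's right endpoint `i/n <= t` — biases
boundary items toward set C; at `n = 8` that single-item bias is visible
(it would move the component straddling the B/C limit of the worked
eigenvalue example into set C), while at the sample sizes of the
simulation checks the two conventions agree. Ties in the data get
consecutive ranks in stable input order, and membership is decided by
rank, never by value, so a tie may straddle a set boundary but every item
has exactly one set.

## Theoretical curves

Families with closed forms use them directly: equality (`p`), uniform on
`[a, a+b]` (`((a+b)p - bp^2/2)/(a + b/2)`), exponential (`p - p log p`,
rate-free), Pareto (`p^((alpha-1)/alpha)`, requiring `alpha > 1` so the
mean exists). Lognormal, Gaussian and chi-squared curves are built from
the definition `ABC(p) = E[X; X > q(1-p)] / E[X]`: the tail mass is
integrated by adaptive quadrature *on the log scale* (`x = e^w`), which
tames the dynamic range of heavy tails — a lognormal with `sdlog = 3`
spans nine orders of magnitude between the cutoffs the optimiser probes —
and is split at the median so the quadrature always brackets the density
bump. The profit gain needs no quadrature at all: differentiating the
tail integral gives `dABC(p) = q(1 - p) / E[X]` exactly. Accuracy is
driven well below the 1e-6 target; tests compare against independent
closed-form tail identities (normal-quantile form for the lognormal, the
mean-plus-density form for the Gaussian, the `df + 2` cdf identity for
the chi-squared).

ABC curves require non-negative values, and the Gaussian has support on
the whole line. The package computes Gaussian curves on the positive part
of the distribution and requires `mean/sd >= 4`, which keeps the clipped
mass below 3.2e-5 — negligible at curve accuracy — while admitting the
narrow bell shapes (such as N(5, 1)) for which a Gaussian ABC curve is
meaningful at all; wider ones raise an error asking for explicit
truncation or shifting rather than silently analysing a distribution that
is one-third negative.

## The samplers

`abc_sample()` draws reproducible fixtures for the seven families with a
caller-supplied seed, leaving the global RNG state untouched. Gaussian
draws below zero are clipped to zero with a warning and a `clipped`
attribute — the sampler mirrors what a practitioner must do to feed such
data into an ABC analysis. The samplers emulate ideal i.i.d. draws only:
real data has measurement error, dependence and mixture structure that no
single named family reproduces, so passing the simulation checks shows
the machinery recovers known curve geometry, not that any particular real
data set is, say, lognormal.

Simulation sizes used in the checks were chosen to keep the suite fast
while leaving comfortable margins: n = 10,000 for sampled-curve limit
points (sampling error in the limit efforts is then well under one
percentage point), n = 100,000 for the empirical-to-analytic sup-norm
convergence bound of 0.01, and n in {8, 50, 1000} for optimiser-oracle
equivalence.

## Component retention

`select_components()` runs the analysis on an eigenvalue spectrum and
retains sets A and B — set C is what the analysis says you may discard.
The comparison baseline, the Kaiser-Guttman rule, retains eigenvalues
*strictly* greater than 1 (a component at exactly 1.0 carries no more
variance than an average input variable and is excluded). Cumulative
explained variance is always recomputed from the eigenvalues rather than
taken from any rounded percent column supplied alongside. Matrix input is
eigendecomposed as given — no centering or scaling — because which matrix
(covariance vs correlation) to analyse is a modelling decision that
belongs upstream.

## Known limitations

* The spline is *a* monotone concavity-preserving quadratic interpolant;
  other valid interpolants of the same points can move the limit points
  by a few hundredths at very small `n`, and published analyses based on
  a different interpolation may disagree with this package in the second
  decimal of a threshold.
* Items are unweighted: each contributes effort `1/n` by definition.
  Weighted variants would change the effort axis and are out of scope.
* Negative values are always rejected; zeros are allowed (with a warning)
  but a large share of zeros makes the curve degenerate toward the
  winner-takes-all shape and the B/C limit less informative.
* The Pareto family needs `alpha > 1`; at `alpha <= 1` the mean diverges
  and no ABC curve exists.
* The scree-plot "elbow" is drawn in plots for orientation but never
  computed — it has no agreed mathematical definition, which is the
  motivation for the computed limits in the first place.
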