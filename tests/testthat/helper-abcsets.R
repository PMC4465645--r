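# Shared fixtures and independent oracles. Everything here is built in
# code; the only external numbers are the published eigenvalues of the
# eight pain-threshold principal components.

pain_eigenvalues <- c(3.834, 1.142, 1.061, 0.740, 0.491, 0.432, 0.208, 0.092)

# Closed-form ABC curve of Uniform[0, b] and its slope, used as the
# analytic oracle against spline-based results.
unif_abc <- function(p) -p^2 + 2 * p
unif_gain <- function(p) -2 * p + 2

# Exhaustive grid-scan minimiser: the brute-force oracle for the optimizer
# equivalence checks (step 1e-5 unless stated otherwise).
grid_argmin <- function(f, lower = 0, upper = 1, step = 1e-5) {
  grid <- seq(lower, upper, by = step)
  grid[which.min(f(grid))]
}

# Frozen oracle values for the Uniform[0, b] closed form, computed by
# brute-force minimisation at step 1e-6 of
#   p^2 + (1 - ABC(p))^2        (Pareto point) and
#   (p - 1/2)^2 + (1 - ABC(p))^2 (SubMarginal point, BreakEven at 1/2):
unif_pareto_effort <- 0.410245
unif_submarginal_effort <- 0.614542

sup_dist <- function(f, g, grid = seq(0, 1, by = 1e-3)) {
  max(abs(f(grid) - g(grid)))
}

# Skewed positive test data with a fixed stream, for property loops.
random_positive <- function(n, seed) {
  set.seed(seed)
  rlnorm(n, meanlog = 0, sdlog = sample(c(0.5, 1, 2), 1)) + runif(n)
}
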