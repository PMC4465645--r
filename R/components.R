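# Principal-component retention by ABC analysis, compared with the
# Kaiser-Guttman criterion.

#' Select principal components to retain via ABC analysis
#'
#' Runs an ABC analysis on a spectrum of eigenvalues (variance components)
#' and retains the components in sets A and B — the "important few" plus
#' the proportional middle — while set C collects the "trivial many" that
#' add yield only at over-proportional cost. The result is compared against
#' the Kaiser-Guttman criterion, which retains components with eigenvalue
#' strictly greater than 1.
#'
#' Both retention rules select a prefix of the decreasingly sorted
#' spectrum; eigenvalues supplied in any order are sorted first. Cumulative
#' explained variance is computed from the eigenvalues themselves,
#' `100 * sum(retained) / sum(all)`.
#'
#' @param x Eigenvalues as a numeric vector, a data frame (with `value`
#'   naming the column), or a symmetric matrix (covariance or correlation),
#'   whose eigendecomposition is taken as given — no centering or scaling
#'   is applied. At least 3 non-negative eigenvalues, not all zero.
#' @param value For data frames, the eigenvalue column (defaults to the
#'   first numeric column).
#' @param ... Passed between methods.
#' @return An object of class `abc_components`: a list with the
#'   per-component tibble (`component`, `eigenvalue`, `explained_pct`,
#'   `cumulative_pct`, `set`, `retained_abc`, `retained_kaiser`), the two
#'   cumulative-variance percentages, and the underlying [abc_analysis()].
#' @examples
#' eig <- c(3.834, 1.142, 1.061, 0.740, 0.491, 0.432, 0.208, 0.092)
#' sel <- select_components(eig)
#' glance(sel)
#' @export
select_components <- function(x, ...) UseMethod("select_components")

#' @rdname select_components
#' @export
select_components.data.frame <- function(x, value = NULL, ...) {
  select_components(pull_values(x, {{ value }}), ...)
}

#' @rdname select_components
#' @export
select_components.matrix <- function(x, ...) {
  if (nrow(x) != ncol(x) || max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x)))) {
    abort("matrix input must be square and symmetric")
  }
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev)))) {
    abort("matrix has substantially negative eigenvalues; not a covariance/correlation matrix")
  }
  select_components(pmax(ev, 0), ...)
}

#' @rdname select_components
#' @export
select_components.numeric <- function(x, ...) {
  if (length(x) < 3) {
    abort("need at least 3 eigenvalues")
  }
  lambda <- sort(validate_values(x), decreasing = TRUE)
  fit <- abc_analysis(lambda)
  part <- fit$partition # already in rank order
  total <- sum(lambda)
  comp <- tibble::tibble(
    component = seq_along(lambda),
    eigenvalue = lambda,
    explained_pct = 100 * lambda / total,
    cumulative_pct = 100 * cumsum(lambda) / total,
    set = part$set,
    retained_abc = part$set %in% c("A", "B"),
    retained_kaiser = lambda > 1
  )
  structure(
    list(
      components = comp,
      cumulative_variance_abc = 100 * sum(lambda[comp$retained_abc]) / total,
      cumulative_variance_kaiser = 100 * sum(lambda[comp$retained_kaiser]) / total,
      analysis = fit
    ),
    class = "abc_components"
  )
}

#' @export
print.abc_components <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<abc_components: %d components | ABC retains %d (%.1f%% variance), Kaiser-Guttman %d (%.1f%%)>\n",
    g$n_components, g$n_retained_abc, g$cumulative_variance_abc,
    g$n_retained_kaiser, g$cumulative_variance_kaiser
  ))
  print(x$components)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.abc_components <- function(x, ...) {
  x$components
}

#' @exportS3Method generics::glance
glance.abc_components <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    n_retained_abc = sum(x$components$retained_abc),
    n_retained_kaiser = sum(x$components$retained_kaiser),
    cumulative_variance_abc = x$cumulative_variance_abc,
    cumulative_variance_kaiser = x$cumulative_variance_kaiser,
    t_ab = x$analysis$limits$t_ab,
    t_bc = x$analysis$limits$t_bc
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.abc_components <- function(object, ...) {
  comp <- object$components
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$component,
                                     y = .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set), size = 2.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "magenta") +
    ggplot2::scale_colour_manual(values = c(A = "#D55E00", B = "#0072B2",
                                            C = "grey55")) +
    ggplot2::labs(x = "component", y = "eigenvalue", colour = "ABC set",
                  title = "Scree plot with ABC sets",
                  subtitle = "dashed line: Kaiser-Guttman threshold (eigenvalue > 1)") +
    ggplot2::theme_minimal()
}
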