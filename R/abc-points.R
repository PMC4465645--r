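#' Discrete effort-yield (ABC) points of a data vector
#'
#' Sorts the values in decreasing order and computes, for every rank
#' `i = 1, ..., n`, the effort `E_i = i/n` (fraction of items considered) and
#' the yield `Y_i` (fraction of the total sum contributed by the `i` largest
#' values). The pair sequence `(E_i, Y_i)` is the discrete ABC representation
#' from which the continuous ABC curve is interpolated.
#'
#' Values must be non-negative and not all zero. Ties are broken by stable
#' original order, so equal values receive consecutive ranks in input order;
#' set membership downstream is decided by rank, never by value. Zeros are
#' permitted (the curve stays defined) but are flagged with a warning since
#' items with zero weight contribute effort without yield.
#'
#' @param data A data frame with at least one non-negative numeric column, or
#'   a bare numeric vector.
#' @param value For data frames, the column holding the values
#'   (tidyselect-style name or position). Defaults to the first numeric
#'   column.
#' @param ... Passed between methods.
#'
#' @return A tibble of class `abc_points` with one row per item, ordered by
#'   decreasing value: `item` (original input position), `value`, `rank`,
#'   `effort`, `yield`. The total sum is kept in the `total` attribute.
#'
#' @examples
#' eig <- c(3.834, 1.142, 1.061, 0.740, 0.491, 0.432, 0.208, 0.092)
#' pts <- abc_points(eig)
#' pts$yield[4] # the four largest carry ~85% of the total
#' @export
abc_points <- function(data, ...) UseMethod("abc_points")

#' @rdname abc_points
#' @export
abc_points.data.frame <- function(data, value = NULL, ...) {
  abc_points(pull_values(data, {{ value }}), ...)
}

#' @rdname abc_points
#' @export
abc_points.default <- function(data, ...) {
  abort("values must be numeric")
}

#' @rdname abc_points
#' @export
abc_points.numeric <- function(data, ...) {
  x <- validate_values(data)
  n <- length(x)
  ord <- order(x, decreasing = TRUE) # stable: ties keep input order
  xs <- x[ord]
  cum <- cumsum(xs)
  out <- tibble::tibble(
    item   = ord,
    value  = xs,
    rank   = seq_len(n),
    effort = seq_len(n) / n,
    yield  = cum / cum[n]
  )
  attr(out, "total") <- cum[n]
  class(out) <- c("abc_points", class(out))
  out
}

# Shared input contract: finite, non-negative, positive total.
validate_values <- function(x, n_min = 1L) {
  if (!is.numeric(x)) {
    abort("values must be numeric")
  }
  if (length(x) < n_min) {
    abort(sprintf("need at least %d values, got %d", n_min, length(x)))
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0) {
    abort(sprintf("non-finite value at position %d", bad[1]))
  }
  neg <- which(x < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative value at position %d", neg[1]))
  }
  if (sum(x) <= 0) {
    abort("degenerate total yield: all values are zero")
  }
  nz <- sum(x == 0)
  if (nz > 0) {
    warn(sprintf("%d zero value%s: zero-weight items add effort without yield",
                 nz, if (nz == 1) "" else "s"))
  }
  as.numeric(x)
}

# Column selection for the data-frame-first interface: an explicit
# tidyselect-style column, else the first numeric column.
pull_values <- function(data, value) {
  q <- enquo(value)
  if (!quo_is_null(q)) {
    sel <- tidyselect::eval_select(q, data)
    if (length(sel) != 1) {
      abort("select exactly one value column")
    }
    return(data[[sel]])
  }
  num <- vapply(data, is.numeric, logical(1))
  if (!any(num)) {
    abort("no numeric column found; name one with `value`")
  }
  data[[which(num)[1]]]
}

#' @export
print.abc_points <- function(x, ...) {
  cat(sprintf("<abc_points: %d items, total %.6g>\n", nrow(x), attr(x, "total")))
  NextMethod()
}
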