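# File input, preprocessing, analysis reports and plotting.

#' Read a column of non-negative values from a CSV/TSV file
#'
#' Reads a delimited text file and extracts one numeric column as the data
#' vector for an ABC analysis. The delimiter is auto-detected (tab if the
#' first line contains one, comma otherwise) unless forced; a header row is
#' detected by whether the first line parses as numbers. Cells that do not
#' parse, missing cells and negative values are rejected with the offending
#' row named.
#'
#' @param path Path to the file.
#' @param column Column to use: a name, a 1-based index, or `NULL` for the
#'   first numeric column.
#' @param delim Field delimiter; `NULL` to auto-detect.
#' @return A tibble with the single column `value`, in file order.
#' @export
read_values <- function(path, column = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    abort(sprintf("empty file: %s", path))
  }
  delim <- delim %||% if (grepl("\t", first)) "\t" else ","
  head_cells <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(head_cells))))
  df <- readr::read_delim(path, delim = delim, col_names = has_header,
                          show_col_types = FALSE, progress = FALSE,
                          trim_ws = TRUE)
  col <- if (is.null(column)) {
    num <- which(vapply(df, is.numeric, logical(1)))
    if (length(num) == 0) {
      # single non-numeric column: fall through and report its bad cell
      if (ncol(df) == 1) 1L else abort("no numeric column found")
    } else {
      num[1]
    }
  } else if (is.numeric(column)) {
    if (column < 1 || column > ncol(df)) {
      abort(sprintf("column index %d out of range (file has %d columns)",
                    column, ncol(df)))
    }
    as.integer(column)
  } else {
    idx <- match(column, names(df))
    if (is.na(idx)) {
      abort(sprintf("no column named '%s' (columns: %s)", column,
                    paste(names(df), collapse = ", ")))
    }
    idx
  }
  raw <- df[[col]]
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    abort(sprintf("unparseable or missing value at row %d, column '%s'",
                  bad[1], names(df)[col]))
  }
  neg <- which(v < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative value at row %d", neg[1]))
  }
  tibble::tibble(value = v)
}

#' Rescale data to unit variance without centering
#'
#' Divides the values by their standard deviation. ABC curves are invariant
#' to scaling but *not* to location shifts (adding a constant flattens the
#' curve toward the identity), so this is the only standardization that
#' leaves the analysis untouched; mean-centering is deliberately not
#' offered, as it would both change the curve and produce negative values.
#'
#' @inheritParams abc_points
#' @param unit_variance If `FALSE`, the data is returned unchanged.
#' @return A tibble with the (possibly rescaled) column `value`.
#' @export
scale_to_unit_variance <- function(data, value = NULL, unit_variance = TRUE) {
  x <- if (is.data.frame(data)) pull_values(data, {{ value }}) else data
  x <- validate_values(x)
  if (!unit_variance) {
    return(tibble::tibble(value = x))
  }
  s <- sd(x)
  if (!is.finite(s) || s <= 0) {
    abort("cannot scale to unit variance: data has zero variance")
  }
  tibble::tibble(value = x / s)
}

#' Structured report of an ABC analysis
#'
#' Collects the input summary, set limits, partition and provenance of an
#' analysis into a plain list that serializes losslessly to JSON:
#' `write_abc_report()` and `read_abc_report()` round-trip byte-identically.
#' Fractions are reported on `[0, 1]`; converting to percent is left to the
#' presentation layer so the report has a single unit convention.
#'
#' @param analysis An [abc_analysis()] result.
#' @param seed Optional integer seed recorded in the provenance block.
#' @param preprocessing Label of any preprocessing applied upstream.
#' @param report A report list as returned by `abc_report()`.
#' @param path File path for the JSON report.
#' @return `abc_report()` returns the report list; `write_abc_report()`
#'   returns `path` invisibly; `read_abc_report()` returns the parsed list.
#' @export
abc_report <- function(analysis, seed = NULL, preprocessing = "none") {
  stopifnot(inherits(analysis, "abc_analysis"))
  g <- glance(analysis)
  part <- analysis$partition
  pt <- function(p) list(effort = p$effort[1], yield = p$yield[1],
                         gain = p$gain[1])
  idx <- function(s) as.integer(sort(part$item[part$set == s]))
  report <- list(
    input = list(
      n = nrow(part),
      n_zero = sum(part$value == 0),
      preprocessing = preprocessing
    ),
    limits = list(
      t_ab = g$t_ab,
      t_bc = g$t_bc,
      swapped = g$swapped,
      degenerate = if (is.na(g$degenerate)) NULL else g$degenerate,
      pareto = pt(analysis$limits$pareto),
      break_even = pt(analysis$limits$break_even),
      submarginal = pt(analysis$limits$submarginal)
    ),
    partition = list(
      counts = list(A = g$n_a, B = g$n_b, C = g$n_c),
      yield_share = list(A = g$yield_a, B = g$yield_b, C = g$yield_c),
      sets = list(A = idx("A"), B = idx("B"), C = idx("C"))
    ),
    provenance = list(
      package = "abcsets",
      version = as.character(packageVersion("abcsets")),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      config_hash = rlang::hash(list(part$value, preprocessing))
    )
  )
  report
}

#' @rdname abc_report
#' @export
write_abc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname abc_report
#' @export
read_abc_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' ABC plot of an analysis
#'
#' Draws the unit-square ABC plot: the interpolated ABC curve with its
#' discrete effort-yield points, the identity and uniform-in-data-range
#' reference curves, the anti-diagonal `Y = 1 - E` (where yield equals the
#' remaining effort), the Pareto / BreakEven / SubMarginal points and
#' vertical red lines at the set limits.
#'
#' @param object,analysis An [abc_analysis()] result.
#' @param references Draw the identity and uniform-in-range curves?
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.abc_analysis <- function(object, references = TRUE, ...) {
  grid <- seq(0, 1, length.out = 513)
  curve_df <- tibble::tibble(effort = grid,
                             yield = object$curve$evaluate(grid))
  pts <- tibble::as_tibble(object$points)
  marks <- tidy(object$limits)
  marks$label <- c("Pareto", "BreakEven", "SubMarginal")
  p <- ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$effort,
                                              y = .data$yield))
  if (references) {
    refs <- reference_curves(pts$value)
    ref_df <- dplyr::bind_rows(
      tibble::tibble(effort = grid,
                     yield = refs$identity$evaluate(grid),
                     which = "identity"),
      tibble::tibble(effort = grid,
                     yield = refs$uniform_in_range$evaluate(grid),
                     which = "uniform in range")
    )
    p <- p + ggplot2::geom_line(
      data = ref_df,
      ggplot2::aes(linetype = .data$which),
      colour = c("magenta", "darkgreen")[match(ref_df$which,
                                               c("identity",
                                                 "uniform in range"))]
    )
  }
  p +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(object$limits$t_ab,
                                       object$limits$t_bc),
                        colour = "red") +
    ggplot2::geom_line(colour = "blue") +
    ggplot2::geom_point(data = pts, size = 1, colour = "blue") +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(shape = .data$label), size = 3,
                        colour = c("red", "darkgreen", "blue")) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "effort (fraction of items)",
                  y = "yield (fraction of total)",
                  shape = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.abc_analysis
#' @param path Output image path; format from the extension (`.png` or
#'   `.pdf`).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @export
plot_abc <- function(analysis, path, references = TRUE,
                     width = 6, height = 6, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf")) {
    abort("plot format must be .png or .pdf")
  }
  p <- autoplot(analysis, references = references)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi)
  invisible(path)
}
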