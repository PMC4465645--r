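Package: abcsets
Title: Computed ABC Analysis with Mathematically Precise Set Limits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computed ABC analysis for selecting the "important few" items
    from skewed non-negative data such as principal-component eigenvalues,
    effect sizes or abundances. Builds effort-yield (ABC) curves from the
    decreasingly sorted data via a shape-preserving quadratic spline,
    locates the Pareto, BreakEven and SubMarginal points on the curve, and
    partitions the items into sets A ("important few"), B (intermediate)
    and C ("trivial many") from the derived set limits. Includes closed-form
    and quantile-based ABC curves for standard distributions, the Lorenz
    curve duality, Pareto shape calibration to the Juran 20/80 point, an
    application to principal-component retention compared against the
    Kaiser-Guttman criterion, seeded samplers for the supported families,
    ggplot2 visualisations, JSON analysis reports and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyselect,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
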