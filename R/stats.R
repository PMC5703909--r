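#' Box-plot summary with 5th/95th-percentile whiskers
#'
#' Median, quartiles and the 5th/95th percentiles (the whisker convention
#' used throughout: center line = median, box = 25th-75th percentile,
#' whiskers = 5th-95th percentile), computed by linear interpolation
#' between order statistics (inclusive convention, `stats::quantile`
#' type 7).
#'
#' @param values Numeric vector (non-finite values dropped with a
#'   warning).
#' @return A one-row tibble: `p5`, `q25`, `median`, `q75`, `p95`, `n`.
#' @export
boxplot_summary <- function(values) {
  bad <- !is.finite(values)
  if (any(bad)) {
    warn(sprintf("%d non-finite value(s) dropped", sum(bad)))
    values <- values[!bad]
  }
  if (length(values) == 0L) abort("no finite values")
  q <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                names = FALSE)
  tibble(p5 = q[1], q25 = q[2], median = q[3], q75 = q[4], p95 = q[5],
         n = length(values))
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' The U statistic is computed from rank sums with average ranks for
#' ties. The two-sided p-value is exact (full enumeration of the null
#' distribution) when both groups have at most 10 observations and there
#' are no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections. The method used is recorded.
#'
#' @param group_a,group_b Numeric vectors (n >= 1 each).
#' @param alpha Significance level for the `significant` flag (default
#'   0.001, the convention adopted for population comparisons).
#' @return An object of class `mw_test` with fields `U`, `p`, `n_a`,
#'   `n_b`, `method` ("exact" or "normal_approx"), `alpha`,
#'   `significant`. Has [tidy()] and [glance()] methods.
#' @export
mann_whitney <- function(group_a, group_b, alpha = 0.001) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  na <- length(group_a); nb <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && na <= 10L && nb <= 10L
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  p <- min(1, wt$p.value)
  structure(list(U = unname(wt$statistic), p = p, n_a = na, n_b = nb,
                 method = if (exact) "exact" else "normal_approx",
                 alpha = alpha, significant = p < alpha),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank sum test (%s)\n", x$method))
  cat(sprintf("  U = %g, n = %d vs %d, two-sided p = %.4g%s\n",
              x$U, x$n_a, x$n_b, x$p,
              if (x$significant) sprintf("  (significant at %g)", x$alpha)
              else ""))
  invisible(x)
}

#' Tidy a Mann-Whitney test
#' @param x An `mw_test`.
#' @param ... Unused.
#' @return One-row tibble: `U`, `p`, `n_a`, `n_b`, `method`,
#'   `significant`.
#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(U = x$U, p = x$p, n_a = x$n_a, n_b = x$n_b, method = x$method,
         significant = x$significant)
}

#' @rdname tidy.mw_test
#' @method glance mw_test
#' @export
glance.mw_test <- function(x, ...) tidy.mw_test(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Histogram of per-cell intensities
#'
#' Left-closed, right-open bins (the last bin closed on both sides); the
#' counts always sum to the number of finite input values, and the number
#' of dropped non-finite values is reported as an attribute.
#'
#' @param values Numeric vector.
#' @param bins Number of equal-width bins, or an explicit vector of bin
#'   edges (length >= 2, increasing).
#' @return A tibble: `bin_left`, `bin_right`, `mid`, `count`; attribute
#'   `dropped` = number of non-finite values removed.
#' @export
intensity_histogram <- function(values, bins = 30) {
  bad <- !is.finite(values)
  values <- values[!bad]
  if (length(values) == 0L) abort("no finite values")
  edges <- if (length(bins) == 1L) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    stopifnot(length(bins) >= 2L, all(diff(bins) > 0))
    as.numeric(bins)
  }
  if (any(values < edges[1] | values > edges[length(edges)]))
    abort("values fall outside the supplied bin edges")
  h <- graphics::hist(values, breaks = edges, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  out <- tibble(bin_left = utils::head(edges, -1),
                bin_right = edges[-1],
                mid = h$mids, count = h$counts)
  attr(out, "dropped") <- sum(bad)
  out
}

#' Compare a metric across strains
#'
#' The population-report workhorse: per-group box-plot summaries plus
#' pairwise Mann-Whitney tests of every group against a designated
#' reference. For the segregation symmetry coefficient S, rows are first
#' restricted to two-focus cells (the convention for symmetry analyses);
#' pass `two_focus_only = FALSE` to override. Raw p-values are reported
#' per comparison (no multiple-testing correction); the number of
#' comparisons is included so users can adjust. Output is invariant to
#' input row order.
#'
#' @param data Tibble with one row per cell.
#' @param metric Name of the value column (`"S"`, `"D_min"`,
#'   `"fraction"`, `"pcc"`, ...).
#' @param group Name of the grouping column (default `"strain"`).
#' @param reference Reference group level (default: first in sorted
#'   order).
#' @param alpha Significance level (default 0.001).
#' @param two_focus_only Restrict to `n_foci == 2` (default: `TRUE` when
#'   `metric == "S"` and an `n_foci` column exists).
#' @return A `strain_comparison` object: list with `$summary` (per-group
#'   [boxplot_summary()] rows), `$tests` (one row per non-reference
#'   group: `group`, `U`, `p`, `n_a`, `n_b`, `method`, `significant`),
#'   `$metric`, `$reference`, `$alpha`, `$n_comparisons`, `$empty_groups`.
#' @export
compare_strains <- function(data, metric, group = "strain",
                            reference = NULL, alpha = 0.001,
                            two_focus_only = NULL) {
  stopifnot(metric %in% names(data), group %in% names(data))
  if (is.null(two_focus_only))
    two_focus_only <- metric == "S" && "n_foci" %in% names(data)
  if (two_focus_only) {
    if (!"n_foci" %in% names(data))
      abort("`two_focus_only` requires an `n_foci` column")
    data <- dplyr::filter(data, .data$n_foci == 2L)
  }
  data <- data[is.finite(data[[metric]]), ]
  groups <- sort(unique(as.character(data[[group]])))
  if (length(groups) < 2L) abort("need at least two non-empty groups")
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) abort("reference group is empty or absent")
  vals <- lapply(setNames(groups, groups),
                 function(g) data[[metric]][data[[group]] == g])
  empty <- names(vals)[vapply(vals, length, integer(1)) == 0L]
  vals <- vals[vapply(vals, length, integer(1)) > 0L]
  summary <- bind_rows(lapply(names(vals), function(g)
    mutate(boxplot_summary(vals[[g]]), group = g, .before = 1)))
  others <- setdiff(names(vals), reference)
  tests <- bind_rows(lapply(others, function(g) {
    mw <- mann_whitney(vals[[reference]], vals[[g]], alpha)
    mutate(tidy(mw), group = g, .before = 1)
  }))
  structure(list(summary = summary, tests = tests, metric = metric,
                 reference = reference, alpha = alpha,
                 n_comparisons = length(others), empty_groups = empty,
                 data = tibble(group = as.character(data[[group]]),
                               value = data[[metric]])),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %s across %d groups (reference: %s)\n",
              x$metric, nrow(x$summary), x$reference))
  print(x$summary)
  cat(sprintf("\nPairwise Mann-Whitney vs %s (%d comparison(s), raw p):\n",
              x$reference, x$n_comparisons))
  print(x$tests)
  invisible(x)
}

#' Plot a strain comparison as box plots with 5-95% whiskers
#'
#' @param object A `strain_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot strain_comparison
#' @export
autoplot.strain_comparison <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median,
                                        ymin = .data$q25,
                                        ymax = .data$q75),
                           width = 0.5, fill = "grey85") +
    ggplot2::labs(x = NULL, y = object$metric,
                  caption = sprintf(
                    "box: 25-75%%, line: median, whiskers: 5-95%%; n = %s",
                    paste(s$n, collapse = ", "))) +
    ggplot2::theme_classic()
}
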