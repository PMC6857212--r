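#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Tests observed phenotype class counts against an expected segregation
#' ratio such as 3:1 (dominant monogenic F2) or 9:3:3:1. The statistic is
#' `sum((O - E)^2 / E)` with `E = total * proportion`; the p-value is the
#' upper tail of the chi-square distribution at `classes - 1` degrees of
#' freedom. No continuity correction is applied by default; the Yates
#' correction (subtract 0.5 from each `|O - E|`, two classes only) is
#' available via `yates = TRUE`.
#'
#' @param observed Integer vector of observed class counts (>= 2 classes).
#' @param ratio Expected ratio, either a numeric vector (`c(3, 1)`) or a
#'   string (`"3:1"`, `"9:3:3:1"`); normalised to proportions internally.
#' @param yates Apply the Yates continuity correction (2 classes only).
#' @return A `segregation_test` object; see [tidy.segregation_test()].
#' @examples
#' chi_square_gof(c(190, 65), "3:1")
#' @export
chi_square_gof <- function(observed, ratio, yates = FALSE) {
  if (is.character(ratio)) {
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  }
  if (length(observed) < 2L) abort("need at least two classes")
  if (length(ratio) != length(observed)) abort("ratio and observed must have the same length")
  if (anyNA(observed) || any(observed < 0) || sum(observed) <= 0) {
    abort("observed counts must be non-negative with a positive total")
  }
  prop <- ratio / sum(ratio)
  expected <- sum(observed) * prop
  if (any(expected == 0)) abort("expected count of zero in some class")
  if (yates && length(observed) != 2L) {
    abort("the Yates correction applies to two classes only")
  }
  dev <- abs(observed - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  structure(
    list(observed = observed, expected = expected, ratio = ratio,
         statistic = statistic, df = df,
         p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
         yates = yates),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit vs %s ratio%s\n",
              paste(x$ratio, collapse = ":"),
              if (x$yates) " (Yates-corrected)" else ""))
  cat(sprintf("  observed: %s   expected: %s\n",
              paste(x$observed, collapse = ", "),
              paste(signif(x$expected, 6), collapse = ", ")))
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tidy a segregation test
#'
#' @param x A `segregation_test`.
#' @param ... Unused.
#' @return `tidy()` gives one row per class (observed vs expected);
#'   `glance()` gives a one-row model summary.
#' @method tidy segregation_test
#' @export
tidy.segregation_test <- function(x, ...) {
  tibble(class = seq_along(x$observed), observed = x$observed,
         expected = x$expected, proportion = x$ratio / sum(x$ratio))
}

#' @rdname tidy.segregation_test
#' @method glance segregation_test
#' @export
glance.segregation_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         yates = x$yates, n = sum(x$observed))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
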