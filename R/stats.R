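# Cohort statistics: median/IQR summaries and the two-sided Mann-Whitney test.

#' Median and interquartile range of a group
#'
#' Quartiles by linear interpolation of the order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector, `n >= 1`, finite.
#' @return A `group_summary`: `n`, `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(n = length(values), median = q[2], q1 = q[1], q3 = q[3]),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, median %.4g (IQR %.4g-%.4g)\n",
              x$n, x$median, x$q1, x$q3))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation inference (full enumeration of the `choose(m+n, m)`
#' group labelings) when `m + n <= 12` and the pooled data are untied --
#' feasible and unambiguous for small cohorts -- and the normal approximation
#' with tie and continuity corrections otherwise. Only the two-sided
#' alternative is exposed. `U` follows the convention of the number of
#' `(x, y)` pairs with `x > y` (ties counted half), so `U_x + U_y = m * n`.
#'
#' @param x,y Numeric samples, each `n >= 1`.
#' @param exact_max Largest `m + n` for which exact enumeration is used
#'   (default 12).
#' @return A `mw_test` list: `U` (for `x`), `p`, `method` (`"exact"` or
#'   `"normal"`), `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups need n >= 1", call. = FALSE)
  m <- length(x)
  n <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (m + n) <= exact_max && !ties
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(U = m * n / 2, p = 1, method = "normal",
                          n_x = m, n_y = n), class = "mw_test"))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  # wilcox.test's W is the Mann-Whitney U for x (pairs with x > y)
  U <- unname(wt$statistic)
  if (ties) {
    r <- rank(c(x, y))
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # half-counts ties
  }
  structure(list(U = U, p = min(wt$p.value, 1),
                 method = if (use_exact) "exact" else "normal",
                 n_x = m, n_y = n),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$U, x$n_x, x$n_y, x$p, x$method))
  invisible(x)
}

#' Compare two groups of values (summary + test)
#'
#' @param a,b Numeric vectors (each `n >= 1`).
#' @param label Name of the compared quantity.
#' @return data.frame row with group medians/IQRs and the Mann-Whitney
#'   result; the test is skipped (NA with a notice column) when either group
#'   has a single member.
#' @export
compare_groups <- function(a, b, label = "value") {
  sa <- median_iqr(a)
  sb <- median_iqr(b)
  if (sa$n < 2 || sb$n < 2) {
    return(data.frame(label = label, n_a = sa$n, median_a = sa$median,
                      q1_a = sa$q1, q3_a = sa$q3, n_b = sb$n,
                      median_b = sb$median, q1_b = sb$q1, q3_b = sb$q3,
                      U = NA_real_, p = NA_real_, method = "skipped",
                      note = "test skipped: a group has a single member"))
  }
  mw <- mann_whitney_u(a, b)
  data.frame(label = label, n_a = sa$n, median_a = sa$median, q1_a = sa$q1,
             q3_a = sa$q3, n_b = sb$n, median_b = sb$median, q1_b = sb$q1,
             q3_b = sb$q3, U = mw$U, p = mw$p, method = mw$method, note = "")
}
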