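#' Integer percentage with half-away-from-zero rounding
#'
#' The rounding convention used by the cohort summary tables: `round(100 *
#' count / total)` with halves rounded away from zero (so 65.5 -> 66), unlike
#' base R's banker's rounding.
#'
#' @param count nonnegative integer, at most `total`.
#' @param total positive integer.
#' @return integer percent.
#' @examples
#' percent(50, 76)  # 66
#' percent(8, 26)   # 31
#' @export
percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0) || any(count > total)) stop("need 0 <= count <= total")
  x <- 100 * count / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Median and interquartile range
#'
#' @param values non-empty numeric vector (`NA` dropped).
#' @param type quantile method: 7 (default, linear interpolation between order
#'   statistics) or 6 (the weighted-average variant used by common commercial
#'   statistics software).
#' @return named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(c(1, 2, 3, 4))  # 2.5, 1.75, 3.25
#' @export
median_iqr <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty values")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Mann-Whitney U test
#'
#' The U statistic is computed from rank sums with midranks for ties. The
#' two-sided p-value is exact (full enumeration of rank assignments) when the
#' combined sample size is at most 12 and there are no ties, and otherwise
#' uses the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y non-empty numeric samples.
#' @return a list with `U` (for `x`), `p` (two-sided) and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (nx + ny) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = U, p = unname(wt$p.value),
       method = if (exact) "exact" else "normal approximation")
}

#' Chi-squared or Fisher's exact test for a 2x2 table
#'
#' Computes the expected counts under independence; if any expected count is
#' below 5 the two-sided Fisher exact test is used (point-probability rule),
#' otherwise the Pearson chi-squared test without continuity correction
#' (Yates' correction selectable).
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param yates apply Yates' continuity correction on the chi-squared branch.
#' @return a list with `test` (`"chi-squared"` or `"fisher"`), `statistic`
#'   (`NA` for Fisher), `p` (two-sided) and `expected`.
#' @examples
#' chi_square_or_fisher(matrix(c(8, 8, 42, 18), 2))  # chi-squared branch
#' @export
chi_square_or_fisher <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (n <= 0) stop("empty table")
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal row or column")
  expected <- outer(rs, cs) / n
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(test = "fisher", statistic = NA_real_, p = unname(ft$p.value),
         expected = expected)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    list(test = "chi-squared", statistic = unname(ct$statistic),
         p = unname(ct$p.value), expected = expected)
  }
}
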