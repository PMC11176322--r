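#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided test of association in a 2x2 contingency table, using the
#' sum-of-small-point-probabilities convention: the p-value is the sum, over
#' all tables with the observed margins, of hypergeometric point
#' probabilities no larger than that of the observed table. This is the
#' convention behind the printed comparisons of mixed-response and
#' new-lesion proportions between patient genotype groups.
#'
#' @param tab A 2x2 matrix of non-negative counts, or the count `a` when
#'   `b`, `c`, `d` are given separately (row 1 = group 1 event/non-event,
#'   row 2 = group 2).
#' @param b,c,d Optional remaining cells when `tab` is scalar.
#' @return A `test_result` list: `statistic` (odds ratio estimate),
#'   `p_value`, `method`, `correction`.
#' @examples
#' fisher_exact_2x2(10, 29, 0, 21)$p_value  # 0.0106
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  tab <- as_table_2x2(tab, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in 2x2 table; p = 1")
    return(test_result(NA_real_, 1, "fisher_exact_two_sided", FALSE))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  test_result(unname(ft$estimate), ft$p.value, "fisher_exact_two_sided", FALSE)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared test of association with df = 1, optionally with
#' the Yates continuity correction. Without correction the statistic equals
#' the closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @inheritParams fisher_exact_2x2
#' @param correct Apply the Yates continuity correction?
#' @return A `test_result` list (`statistic` is the chi-squared statistic).
#' @examples
#' chisq_2x2(matrix(c(12, 12, 19, 5), 2, byrow = TRUE))$p_value  # 0.0346
#' @export
chisq_2x2 <- function(tab, b = NULL, c = NULL, d = NULL, correct = FALSE) {
  tab <- as_table_2x2(tab, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined for a table with an empty margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected count below 5; chi-squared approximation is poor")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  test_result(unname(ct$statistic), ct$p.value,
              if (correct) "chisq_yates" else "chisq_pearson", correct)
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Rank-sum comparison of two samples. Small tie-free samples use exact
#' enumeration; otherwise the normal approximation with tie correction is
#' used. The clinical-style comparisons (per-patient MAD of lesion response,
#' per-tumor diversity metrics) all use the two-sided form.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param correct Continuity correction in the normal approximation.
#' @param exact Force or forbid exact enumeration; default lets sample size
#'   decide (exact when both n <= 20 and there are no ties).
#' @return A `test_result` list (`statistic` is the U statistic for `x`).
#' @examples
#' mann_whitney_u(1:3, 4:6, alternative = "less")$p_value  # 1/20
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           correct = FALSE, exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(test_result(length(x) * length(y) / 2, 1, "mann_whitney_u", correct))
  if (is.null(exact))
    exact <- max(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = correct))
  test_result(unname(wt$statistic), wt$p.value, "mann_whitney_u", correct)
}

#' Unscaled median absolute deviation
#'
#' Median of absolute deviations from the sample median, with no
#' normal-consistency scaling (no 1.4826 factor). Used as the robust
#' measure of per-patient variability in lesion response.
#'
#' @param values Non-empty numeric vector.
#' @return A single number; 0 for constant or single-value input.
#' @examples
#' median_abs_dev(c(-40, -20, 10))  # 20
#' @export
median_abs_dev <- function(values) {
  if (!length(values) || anyNA(values)) stop("values must be non-empty without NA")
  stats::mad(values, constant = 1)
}

test_result <- function(statistic, p_value, method, correction) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 correction = correction),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (isTRUE(x$correction)) " (continuity-corrected)" else ""))
  invisible(x)
}

as_table_2x2 <- function(tab, b, c, d) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, 2, byrow = TRUE)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) < 1) stop("grand total must be >= 1")
  storage.mode(tab) <- "double"
  tab
}
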