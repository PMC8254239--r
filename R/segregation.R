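#' Chi-square goodness-of-fit test for a Mendelian segregation ratio
#'
#' Pearson's chi-square test of observed phenotype-class counts against an
#' expected ratio (default 3:1 for a monogenic recessive in an F2), with no
#' continuity correction. The observed counts are "consistent" with the
#' ratio when the statistic falls below the chi-square critical value at
#' `alpha` on k - 1 degrees of freedom.
#'
#' @param counts Non-negative integer vector of class counts, e.g.
#'   `c(green = 704, yellow = 263)`. Any number of classes >= 2 is accepted
#'   (e.g. a 9:3:3:1 dihybrid ratio).
#' @param ratio Positive expected ratio, same length as `counts`.
#' @param alpha Significance level for the critical value.
#' @return An object of class `chisq_segregation` with fields `statistic`,
#'   `df`, `p_value`, `critical_value`, `consistent`, `observed`,
#'   `expected`, `ratio`, `alpha`.
#' @export
#' @examples
#' chi_square_segregation(c(704, 263))          # F2 3:1 test
#' chi_square_segregation(c(90, 30, 28, 12), ratio = c(9, 3, 3, 1))
chi_square_segregation <- function(counts, ratio = c(3, 1), alpha = 0.05) {
  if (length(counts) < 2 || length(counts) != length(ratio))
    stop("counts and ratio must have the same length (>= 2 classes)")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("total count must be > 0")
  if (any(ratio <= 0)) stop("expected ratio entries must be > 0 (zero expected class)")
  expected <- total * ratio / sum(ratio)
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  critical <- qchisq(1 - alpha, df)
  structure(list(
    statistic = statistic, df = df,
    p_value = pchisq(statistic, df, lower.tail = FALSE),
    critical_value = critical,
    consistent = statistic < critical,
    observed = counts, expected = expected, ratio = ratio, alpha = alpha
  ), class = "chisq_segregation")
}

#' @export
print.chisq_segregation <- function(x, ...) {
  cat(sprintf("Segregation chi-square test (ratio %s)\n",
              paste(x$ratio, collapse = ":")))
  cat(sprintf("  observed: %s   expected: %s\n",
              paste(x$observed, collapse = " / "),
              paste(round(x$expected, 2), collapse = " / ")))
  cat(sprintf("  X-squared = %.2f, df = %d, critical value (alpha=%.2g) = %.2f\n",
              x$statistic, x$df, x$alpha, x$critical_value))
  cat(sprintf("  verdict: %s with the %s ratio (p = %.3g)\n",
              if (x$consistent) "consistent" else "NOT consistent",
              paste(x$ratio, collapse = ":"), x$p_value))
  invisible(x)
}

#' Phenotype-class percentages
#'
#' @param counts Non-negative class counts (total > 0).
#' @param digits Decimal places for rounding (default 1).
#' @return Numeric vector of percentages summing to 100 (within rounding).
#' @export
#' @examples
#' phenotype_fractions(c(green = 704, yellow = 263))  # 72.8 27.2
phenotype_fractions <- function(counts, digits = 1) {
  total <- sum(counts)
  if (total <= 0) stop("total count must be > 0")
  round(100 * counts / total, digits)
}
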