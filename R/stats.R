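#' Chi-square goodness-of-fit test against expected percentages
#'
#' Tests whether observed category counts differ from an expected
#' distribution given as percentages: `E_i = p_i * sum(O)` and
#' `chi2 = sum (O_i - E_i)^2 / E_i`, with `N - 1` degrees of freedom and
#' an upper-tail critical value at the chosen significance level.
#'
#' The percentages are used exactly as supplied, without renormalisation;
#' sums may deviate from 1 by up to `tol` (rounded percentage sets like
#' 33.3/33.4/33.3 or 60.14/14.55/25.3 sum to 0.999-1.0001).
#'
#' @param observed Non-negative integer counts, length >= 2.
#' @param expected_pct Expected proportions (e.g. `c(0.333, 0.334, 0.333)`),
#'   same length.
#' @param alpha Significance level (default 0.05).
#' @param tol Allowed deviation of `sum(expected_pct)` from 1.
#' @return List of class `"chi_square_test"`: `observed`, `expected_pct`,
#'   `expected`, `statistic`, `df`, `critical`, `alpha`, `p_value`,
#'   `significant`.
#' @examples
#' chi_square(c(137, 188, 248), c(0.333, 0.334, 0.333))$statistic  # 32.37
#' @export
chi_square <- function(observed, expected_pct, alpha = 0.05, tol = 0.002) {
  if (length(observed) != length(expected_pct))
    stop("observed and expected_pct must have the same length")
  if (length(observed) < 2L) stop("need at least 2 categories")
  if (abs(sum(expected_pct) - 1) > tol)
    stop("expected percentages sum to ", sum(expected_pct),
         ", outside 1 +/- ", tol)
  E <- expected_pct * sum(observed)
  if (any(E <= 0)) stop("all expected counts must be positive")
  stat <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  crit <- chi2_critical(df, alpha)
  structure(list(observed = observed, expected_pct = expected_pct,
                 expected = E, statistic = stat, df = df,
                 critical = crit, alpha = alpha,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 significant = stat >= crit),
            class = "chi_square_test")
}

#' Upper-tail chi-square critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return The value exceeded with probability `alpha` under the
#'   chi-square distribution with `df` degrees of freedom
#'   (e.g. 5.99 at `df = 2`, `alpha = 0.05`).
#' @export
chi2_critical <- function(df, alpha) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  stats::qchisq(1 - alpha, df = df)
}

#' @export
print.chi_square_test <- function(x, ...) {
  cat(sprintf(
    "Chi-square test: statistic %.4g on %d df; critical %.4g at alpha %.3g -> %s\n",
    x$statistic, x$df, x$critical, x$alpha,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}
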