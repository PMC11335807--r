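#' Power of the one-sample t-test
#'
#' Exact power via the noncentral t distribution: with `n` participants and
#' true standardized effect `d`, the test statistic follows a noncentral t
#' with `n - 1` degrees of freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n Sample size (>= 2).
#' @param d True effect size (Cohen's d against zero).
#' @param alpha Significance level.
#' @param tails `"two"` (default) or `"one"`.
#' @return Probability of rejecting the null.
#' @export
t_test_power <- function(n, d, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  ncp <- d * sqrt(n)
  df <- n - 1
  if (tails == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  } else {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  }
}

#' Required sample size for a one-sample t-test
#'
#' Smallest integer `N >= 2` whose exact noncentral-t power reaches the
#' target. The search brackets around the large-sample normal
#' approximation `((z_(1-alpha/2) + z_power) / d)^2` and then scans for the
#' minimal `N`, so the returned value satisfies power(N) >= target and
#' power(N - 1) < target.
#'
#' @param d True effect size (> 0).
#' @param power Target power (default 0.80).
#' @param alpha Significance level (default 0.05).
#' @param tails `"two"` (default) or `"one"`.
#' @return Integer sample size.
#' @export
#' @examples
#' required_n(0.58) # exact noncentral-t answer for the common scenario
#' required_n(0.66)
required_n <- function(d, power = 0.80, alpha = 0.05,
                       tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!is.finite(d) || d <= 0) stop("d must be strictly positive")
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1)
  za <- if (tails == "two") stats::qnorm(1 - alpha / 2) else
    stats::qnorm(1 - alpha)
  guess <- max(2, ceiling(((za + stats::qnorm(power)) / d)^2) - 5)
  n <- guess
  while (t_test_power(n, d, alpha, tails) < power) n <- n + 1
  while (n > 2 && t_test_power(n - 1, d, alpha, tails) >= power) n <- n - 1
  as.integer(n)
}

#' Sample-size saving from a larger effect size
#'
#' Percentage reduction in the required one-sample t-test sample size when
#' planning with the combined measure's effect size instead of the best
#' single measure's.
#'
#' @param d_single Effect size of the best single measure (> 0).
#' @param d_combined Effect size of the combined measure (> 0).
#' @inheritParams required_n
#' @return Percentage reduction,
#'   `100 * (N(d_single) - N(d_combined)) / N(d_single)`.
#' @export
#' @examples
#' sample_size_reduction(0.58, 0.66)
sample_size_reduction <- function(d_single, d_combined, power = 0.80,
                                  alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n1 <- required_n(d_single, power, alpha, tails)
  n2 <- required_n(d_combined, power, alpha, tails)
  100 * (n1 - n2) / n1
}
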