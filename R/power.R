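# Frequentist power for the two-sample t-test via the noncentral t
# distribution, and the smallest per-group sample size reaching a target
# power. Used to justify group sizes before data collection.

#' Power of a two-sample t-test
#'
#' Exact power from the noncentral t distribution: with `n` per group the
#' test statistic has `2n - 2` degrees of freedom and noncentrality
#' `d * sqrt(n / 2)`.
#'
#' @param n Per-group sample size (`>= 2`).
#' @param d Cohen's d effect size (`> 0`).
#' @param alpha Type-I error rate.
#' @param tails 1 or 2.
#' @return Power (probability of rejecting H0).
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05, tails = 2) {
  if (!is_count(n) || n < 2) abort_ns("`n` must be an integer >= 2", "numsense_invalid_argument")
  if (!is_scalar_num(d) || d <= 0) abort_ns("`d` must be > 0", "numsense_invalid_argument")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1) {
    abort_ns("`alpha` must be in (0, 1)", "numsense_invalid_argument")
  }
  if (!tails %in% c(1, 2)) abort_ns("`tails` must be 1 or 2", "numsense_invalid_argument")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Required per-group sample size for a two-sample t-test
#'
#' Smallest integer `n >= 2` whose noncentral-t power reaches the target.
#' With `d = 1.2`, `alpha = 0.05`, `power = 0.95`, two-tailed, the answer is
#' 20 per group.
#'
#' @param d Cohen's d effect size.
#' @param alpha Type-I error rate.
#' @param power Target power in (0, 1).
#' @param tails 1 or 2.
#' @param n_max Safety cap on the search.
#' @return Required per-group n (integer).
#' @export
required_n_per_group <- function(d, alpha = 0.05, power = 0.95, tails = 2,
                                 n_max = 1e6) {
  if (!is_scalar_num(power) || power <= 0 || power >= 1) {
    abort_ns("`power` must be in (0, 1)", "numsense_invalid_argument")
  }
  n <- 2L
  while (n <= n_max) {
    if (power_two_sample_t(n, d, alpha, tails) >= power) return(n)
    n <- n + 1L
  }
  abort_ns("no n below `n_max` reaches the target power", "numsense_invalid_argument")
}
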