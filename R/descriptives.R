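# Descriptive statistics in the conventions of mainstream GUI statistics
# software (bias-corrected skewness G1 and excess kurtosis G2), plus the
# normality gate that decides between the parametric and rank-based
# two-sample tests.

#' Descriptive statistics for one sample
#'
#' Sample size, mean, sd (n-1 denominator), min, max, and bias-corrected
#' skewness (G1) and excess kurtosis (G2). Moments that are undefined for
#' the sample size (skewness needs `n >= 3`, kurtosis `n >= 4`) or for a
#' constant sample are `NA`.
#'
#' @param x Numeric sample (`n >= 2` after dropping `NA`).
#' @return A list of class `descriptives`.
#' @export
describe <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort_ns("need n >= 2", "numsense_invalid_input")
  m <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  skew <- kurt <- NA_real_
  if (s > 0) {
    if (n >= 3) {
      g1 <- mean((x - m)^3) / m2^1.5
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    }
    if (n >= 4) {
      g2 <- mean((x - m)^4) / m2^2 - 3
      kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  }
  structure(list(n = n, mean = m, sd = s, min = min(x), max = max(x),
                 kurtosis = kurt, skewness = skew),
            class = "descriptives")
}

#' @export
print.descriptives <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.3f (sd %.3f), range [%.3f, %.3f], skew %.3f, kurt %.3f\n",
              x$n, x$mean, x$sd, x$min, x$max, x$skewness, x$kurtosis))
  invisible(x)
}

#' Normality-gated test selection for a two-group comparison
#'
#' Runs a Shapiro-Wilk test on each group and selects the nonparametric
#' (rank-based) comparison if either group rejects normality at
#' `alpha_norm`; otherwise the parametric t-test. The decision is symmetric
#' in the two samples, and the W statistics and p values are returned so the
#' selection can be logged.
#'
#' @param x,y Numeric samples (`n >= 3` each after dropping `NA`).
#' @param alpha_norm Significance level of the normality gate.
#' @return A list with `choice` (`"parametric"` or `"nonparametric"`), `W`
#'   and `p` (length-2 vectors), `alpha_norm`.
#' @export
check_normality_and_select <- function(x, y, alpha_norm = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) abort_ns("need n >= 3 per group", "numsense_invalid_input")
  sx <- stats::shapiro.test(x)
  sy <- stats::shapiro.test(y)
  reject <- c(sx$p.value, sy$p.value) < alpha_norm
  list(choice = if (any(reject)) "nonparametric" else "parametric",
       W = c(unname(sx$statistic), unname(sy$statistic)),
       p = c(sx$p.value, sy$p.value),
       alpha_norm = alpha_norm)
}
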