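# Independent oracles used by the tests. Each one recomputes a quantity the
# package produces, through a different formulation and a different
# numerical method (high-resolution trapezoid rules, closed forms, explicit
# enumeration), so agreement is a genuine cross-check rather than a
# tautology.

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# JZS two-sample Bayes factor via Rouder's g-mixture representation (the
# package integrates the Cauchy prior against the noncentral-t likelihood
# instead): BF10 = E_g[(1 + N g r^2)^{-1/2} (1 + t^2 / ((1 + N g r^2) df))^{-(df+1)/2}]
# / (1 + t^2/df)^{-(df+1)/2}, g ~ InverseGamma(1/2, 1/2).
oracle_jzs_lbf <- function(tstat, n1, n2, r = sqrt(2) / 2, n_grid = 1e5) {
  neff <- n1 * n2 / (n1 + n2)
  df <- n1 + n2 - 2
  u <- seq(-30, 30, length.out = n_grid)
  g <- exp(u)
  a <- 1 + neff * g * r^2
  log_num <- -0.5 * log(a) - (df + 1) / 2 * log1p(tstat^2 / (a * df))
  log_ig <- 0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(g) - 0.5 / g
  integrand <- exp(log_num + log_ig + u)  # times g for the log substitution
  log_den <- -(df + 1) / 2 * log1p(tstat^2 / df)
  (log(trapz(u, integrand)) - log_den) / log(10)
}

pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Gauss hypergeometric series, written independently of the package version.
oracle_2f1 <- function(a, b, cc, z) {
  term <- 1; s <- 1
  for (k in 0:100000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < 1e-16 * abs(s)) break
  }
  s
}

# Pearson-correlation Bayes factor by trapezoid quadrature of the exact
# likelihood ratio against the stretched-beta prior.
oracle_pearson_lbf <- function(r, n, width = 1, n_grid = 1e5) {
  alpha <- 1 / width
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_grid)
  llr <- (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log(vapply(rho, function(p) oracle_2f1(0.5, 0.5, (2 * n - 1) / 2, (1 + p * r) / 2), numeric(1))) -
    log(oracle_2f1(0.5, 0.5, (2 * n - 1) / 2, 0.5))
  prior <- (1 - rho^2)^(alpha - 1) / (2^(2 * alpha - 1) * beta(alpha, alpha))
  log10(trapz(rho, exp(llr) * prior))
}

# Kendall Bayes factor by trapezoid quadrature of the asymptotic normal
# likelihood of tau-hat against the stretched-beta prior.
oracle_kendall_lbf <- function(tau_hat, n, width = 1, n_grid = 1e5) {
  alpha <- 1 / width
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  tt <- seq(-1, 1, length.out = n_grid)
  prior <- (1 - tt^2)^(alpha - 1) / (2^(2 * alpha - 1) * beta(alpha, alpha))
  m1 <- trapz(tt, dnorm(tau_hat, tt, se) * prior)
  log10(m1 / dnorm(tau_hat, 0, se))
}

# Contingency Bayes factor (independent multinomial, rows fixed) by numeric
# quadrature over the cell probabilities, instead of the closed gamma form:
# H1 integrates each row's binomial likelihood against Beta(a, a); H0
# integrates the pooled column counts against the induced Beta(2a, 2a).
oracle_contingency_lbf <- function(y, a = 1, n_grid = 1e5) {
  th <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  row_m <- function(k, n) {
    trapz(th, th^k * (1 - th)^(n - k) * dbeta(th, a, a))
  }
  m1 <- log(row_m(y[1, 1], sum(y[1, ]))) + log(row_m(y[2, 1], sum(y[2, ])))
  m0 <- log(trapz(th, th^sum(y[, 1]) * (1 - th)^sum(y[, 2]) * dbeta(th, 2 * a, 2 * a)))
  (m1 - m0) / log(10)
}

# Kendall's tau by direct enumeration of all pairs (no tie handling needed
# for continuous data).
oracle_tau_pairs <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  s / (n * (n - 1) / 2)
}

# Negative Bernoulli log-likelihood of a cumulative Gaussian psychometric
# function, written directly from the model definition.
oracle_psy_nll <- function(mu, sigma, lev, k, n) {
  p <- pnorm((log10(lev) - mu) / sigma)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

# Trial counts by level from a trials data frame.
level_counts <- function(trials) {
  tr <- trials[!trials$is_anchor & !is.na(trials$response_many), ]
  lev <- sort(unique(tr$numerosity))
  list(lev = lev,
       k = vapply(lev, function(l) sum(tr$response_many[tr$numerosity == l]), numeric(1)),
       n = vapply(lev, function(l) sum(tr$numerosity == l), numeric(1)))
}

quiet_cli <- function(argv) {
  status <- NULL
  msgs <- capture.output(status <- cli(argv), type = "message")
  list(status = status, messages = msgs)
}
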