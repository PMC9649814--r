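test_that("evidence classification uses strict thresholds", {
  expect_equal(classify_evidence(2.3), "definitive_H1")
  expect_equal(classify_evidence(-0.24), "inconclusive")
  expect_equal(classify_evidence(0.5), "inconclusive")  # boundary is strict
  expect_equal(classify_evidence(-0.51), "substantial_H0")
  expect_equal(classify_evidence(1.2), "strong_H1")
  expect_equal(classify_evidence(-2.5), "definitive_H0")
})

test_that("every Bayes factor respects BF10 * BF01 = 1", {
  set.seed(101)
  x <- rnorm(20); y <- rnorm(20, 0.6)
  for (bf in list(lbf_ttest_two_sample(x, y),
                  lbf_pearson(x, y),
                  lbf_kendall(x, y),
                  lbf_contingency_2x2(matrix(c(12, 8, 6, 14), 2)),
                  lbf_mannwhitney(x, y, draws = 500, warmup = 200, seed = 1))) {
    expect_equal(bf$bf10 * (1 / bf$bf10), 1)
    expect_equal(log10(bf$bf10), bf$lbf, tolerance = 1e-12)
  }
})

test_that("the JZS t-test favors the null at t = 0 and grows with |t|", {
  x <- c(-2, -1, 0, 1, 2)
  expect_lt(lbf_ttest_two_sample(rep(x, 4), rep(x, 4))$lbf, 0)
  # monotone in the shift (hence in |t|) at fixed samples
  set.seed(5)
  base_x <- rnorm(20); base_y <- rnorm(20)
  lbfs <- vapply(seq(0, 2, by = 0.25),
                 function(s) lbf_ttest_two_sample(base_x, base_y + s)$lbf, numeric(1))
  start <- which.min(lbfs)
  expect_true(all(diff(lbfs[start:length(lbfs)]) > 0))
  # with t pinned at 0, more data mean more support for the null
  lbf_n <- vapply(c(2, 5, 20, 80),
                  function(k) lbf_ttest_two_sample(rep(x, k), rep(x, k))$lbf, numeric(1))
  expect_true(all(diff(lbf_n) < 0))
  expect_error(lbf_ttest_two_sample(rep(1, 5), rep(2, 5)), class = "numsense_degenerate")
})

test_that("JZS t-test agrees with the g-mixture quadrature oracle", {
  set.seed(202)
  for (i in 1:20) {
    n1 <- sample(10:30, 1); n2 <- sample(10:30, 1)
    d <- runif(1, 0, 1.5)
    x <- rnorm(n1); y <- rnorm(n2, d)
    got <- lbf_ttest_two_sample(x, y)
    want <- oracle_jzs_lbf(pooled_t(x, y), n1, n2)
    expect_lt(abs(got$lbf - want), 1e-3)
  }
})

test_that("Pearson BF behaves at its limits and matches its oracle", {
  set.seed(7)
  x <- rnorm(20)
  expect_lt(lbf_pearson(x, rnorm(20))$lbf, 0.5)
  expect_gt(lbf_pearson(1:10, 1:10)$lbf, 1)  # collinear: diverges
  z <- rnorm(40); e <- rnorm(40)
  xy <- cbind(z, 0.6 * z + 0.8 * e)
  got <- lbf_pearson(xy[, 1], xy[, 2])
  expect_lt(abs(got$lbf - oracle_pearson_lbf(got$statistic[["r"]], 40)), 1e-4)
  expect_error(lbf_pearson(rep(1, 10), rnorm(10)), class = "numsense_degenerate")
})

test_that("Kendall tau and its BF match enumeration and quadrature oracles", {
  # tau by exhaustive pair counting on the 3-pair toy case
  expect_equal(kendall_tau(c(1, 2, 3), c(2, 1, 3)), 1 / 3)
  expect_equal(oracle_tau_pairs(c(1, 2, 3), c(2, 1, 3)), 1 / 3)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(kendall_tau(x, y), oracle_tau_pairs(x, y))
    expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"))
  }
  # perfectly concordant pairs
  conc <- lbf_kendall(1:10, (1:10)^2)
  expect_equal(conc$statistic[["tau"]], 1)
  expect_gt(conc$lbf, 0)
  expect_error(lbf_kendall(rep(1, 5), rep(2, 5)), class = "numsense_undefined_tau")
  # oracle agreement on seeded data
  for (i in 1:20) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    got <- lbf_kendall(x, y)
    expect_lt(abs(got$lbf - oracle_kendall_lbf(got$statistic[["tau"]], n)), 1e-3)
  }
})

test_that("contingency BF is exact, symmetric, and sane at the limits", {
  expect_lt(lbf_contingency_2x2(matrix(10, 2, 2))$lbf, 0)
  expect_gt(lbf_contingency_2x2(matrix(c(20, 0, 0, 20), 2))$lbf, 1)
  set.seed(13)
  for (i in 1:20) {
    y <- matrix(rpois(4, 12) + 1, 2)
    got <- lbf_contingency_2x2(y)
    expect_lt(abs(got$lbf - oracle_contingency_lbf(y)), 1e-3)
    # invariance to transposition and to swapping both row labels
    expect_equal(lbf_contingency_2x2(t(y))$lbf, got$lbf, tolerance = 1e-10)
    expect_equal(lbf_contingency_2x2(y[2:1, ])$lbf, got$lbf, tolerance = 1e-10)
  }
  expect_error(lbf_contingency_2x2(matrix(10, 2, 2), a = 0),
               class = "numsense_invalid_prior")
  expect_error(lbf_contingency_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "numsense_invalid_argument")
  # alternative sampling schemes remain finite and ordered toward the null
  y <- matrix(c(14, 6, 9, 11), 2, byrow = TRUE)
  lbf_im <- lbf_contingency_2x2(y)$lbf
  lbf_h <- lbf_contingency_2x2(y, sampling = "hypergeometric")$lbf
  expect_lt(lbf_h, lbf_im)  # conditioning on more margins is more conservative
})

test_that("the one-sample multinomial test matches direct marginal likelihoods", {
  got <- lbf_multinomial_test(c(23, 17))
  want <- (lbeta(24, 18) - lbeta(1, 1) - 40 * log(0.5)) / log(10)
  expect_equal(got$lbf, want, tolerance = 1e-12)
  expect_lt(lbf_multinomial_test(c(10, 10, 10, 10))$lbf, 0)
  expect_error(lbf_multinomial_test(c(10, 10), p0 = c(0.2, 0.3)),
               class = "numsense_invalid_argument")
})

test_that("the rank-based two-sample test separates and stays calibrated", {
  set.seed(17)
  x <- rnorm(20)
  same <- lbf_mannwhitney(x, sample(x), draws = 2000, warmup = 500, seed = 3)
  expect_lt(same$lbf, 0)
  apart <- lbf_mannwhitney(x, x + 4, draws = 2000, warmup = 500, seed = 4)
  expect_gt(apart$lbf, 1)
  expect_true(is.finite(apart$mc_se))
  # deterministic given the seed
  again <- lbf_mannwhitney(x, x + 4, draws = 2000, warmup = 500, seed = 4)
  expect_identical(apart$lbf, again$lbf)
})

test_that("rank-based and parametric BFs agree closely on normal data", {
  # the rank likelihood discards the scale information carried by the raw
  # values, so agreement is close but not exact; systematic differences stay
  # well inside 0.15 log10 units at these sample sizes
  set.seed(19)
  for (i in 1:6) {
    x <- rnorm(20); y <- rnorm(20, runif(1, 0, 1))
    tt <- lbf_ttest_two_sample(x, y)$lbf
    mw <- lbf_mannwhitney(x, y, draws = 3000, warmup = 1000, seed = 50 + i)
    expect_lt(abs(tt - mw$lbf), 0.15 + 2 * mw$mc_se)
  }
})

test_that("ANCOVA inclusion reduces to the two-model BF and ranks terms sensibly", {
  set.seed(23)
  d <- data.frame(y = c(rnorm(20), rnorm(20, 1.2)),
                  group = rep(c("ctl", "pat"), each = 20),
                  noise = rnorm(40))
  # group-only model space: inclusion BF equals the direct two-model BF,
  # independently computed from the g-mixture quadrature oracle
  red <- lbf_ancova_inclusion(d, dv = "y", r_fixed = sqrt(2) / 2)
  t_direct <- oracle_jzs_lbf(pooled_t(d$y[1:20], d$y[21:40]), 20, 20, r = sqrt(2) / 2)
  expect_lt(abs(red$terms$group$lbf - t_direct), 1e-3)
  # pure-noise covariate: group included, covariate excluded
  full <- lbf_ancova_inclusion(d, dv = "y", covariates = "noise")
  expect_gt(full$terms$group$lbf, 0)
  expect_lt(full$terms$noise$lbf, 0)
  # matched and across-all coincide on an additive space
  matched <- lbf_ancova_inclusion(d, dv = "y", covariates = "noise", method = "matched")
  expect_equal(matched$terms$group$lbf, full$terms$group$lbf)
})

test_that("collinear designs raise an error naming the offending terms", {
  set.seed(29)
  d <- data.frame(y = rnorm(30), group = rep(c("a", "b"), 15), x1 = rnorm(30))
  d$x2 <- 2 * d$x1
  expect_error(lbf_ancova_inclusion(d, dv = "y", covariates = c("x1", "x2")),
               "x1", class = "numsense_collinear")
})

test_that("power analysis reproduces the design sample size", {
  expect_identical(required_n_per_group(1.2, 0.05, 0.95, tails = 2), 20L)
  expect_identical(required_n_per_group(10), 2L)
  # the returned n is minimal
  expect_lt(power_two_sample_t(19, 1.2), 0.95)
  expect_gte(power_two_sample_t(20, 1.2), 0.95)
})

test_that("noncentral-t power matches brute-force simulation", {
  n <- 20; d <- 1.2; reps <- 20000
  set.seed(31)
  X <- matrix(rnorm(n * reps), n); Y <- matrix(rnorm(n * reps, d), n)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- (colSums(X^2) - n * mx^2) / (n - 1)
  vy <- (colSums(Y^2) - n * my^2) / (n - 1)
  tt <- (my - mx) / sqrt((vx + vy) / n)
  crit <- qt(0.975, 2 * n - 2)
  p_mc <- mean(abs(tt) > crit)
  p_th <- power_two_sample_t(n, d)
  expect_lt(abs(p_mc - p_th), 3 * sqrt(p_th * (1 - p_th) / reps))
})

test_that("descriptives follow the bias-corrected moment conventions", {
  d <- describe(c(1, 2, 3))
  expect_equal(d$mean, 2); expect_equal(d$sd, 1); expect_equal(d$skewness, 0)
  const <- describe(rep(4, 10))
  expect_equal(const$sd, 0)
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))
  set.seed(37)
  x <- rnorm(20, 3, 2)^2
  d <- describe(x)
  # direct-formula evaluation of the G1/G2 estimators
  n <- length(x); m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  g2 <- mean((x - m)^4) / mean((x - m)^2)^2 - 3
  expect_equal(d$skewness, g1 * sqrt(n * (n - 1)) / (n - 2), tolerance = 1e-10)
  expect_equal(d$kurtosis, ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
               tolerance = 1e-10)
  skip_if_not_installed("e1071")
  expect_equal(d$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2), tolerance = 1e-12)
})

test_that("the normality gate picks tests symmetrically and logs W", {
  set.seed(41)
  x <- rnorm(20); y <- rnorm(20)
  sel <- check_normality_and_select(x, y)
  expect_equal(sel$choice, "parametric")
  expect_length(sel$W, 2)
  skewed <- rexp(20)
  sel2 <- check_normality_and_select(skewed, y)
  expect_equal(sel2$choice, "nonparametric")
  sel3 <- check_normality_and_select(y, skewed)
  expect_equal(sel3$choice, sel2$choice)
  expect_equal(sort(sel3$W), sort(sel2$W))
})

test_that("false-positive evidence under the null stays rare", {
  # H0 simulation: the share of datasets crossing the substantial-evidence
  # bar must be small (sanity bound, not a calibration claim)
  set.seed(43)
  hits <- vapply(1:400, function(i) {
    lbf_ttest_two_sample(rnorm(20), rnorm(20))$lbf > 0.5
  }, logical(1))
  expect_lt(mean(hits), 0.1)
})
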