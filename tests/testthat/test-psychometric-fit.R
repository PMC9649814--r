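test_that("derived indices follow their defining identities", {
  expect_equal(derive_indices(log10(16), 0), list(pse = 16, jnd_log = 0, wf = 0))
  d <- derive_indices(log10(16), 0.09)
  expect_equal(d$wf, 10^(qnorm(0.75) * 0.09) - 1, tolerance = 1e-12)
  expect_equal(d$wf, 0.150, tolerance = 1e-3)
  # wf equals N75/N50 - 1 where N75/N50 are the 75% and 50% points in dots
  set.seed(8)
  for (i in 1:20) {
    mu <- runif(1, 1, 1.4); sigma <- runif(1, 0.01, 0.3)
    d <- derive_indices(mu, sigma)
    n50 <- 10^mu
    n75 <- 10^(mu + qnorm(0.75) * sigma)
    expect_equal(d$wf, n75 / n50 - 1, tolerance = 1e-12)
    # wf strictly increasing in sigma; pse independent of sigma
    d2 <- derive_indices(mu, sigma + 0.01)
    expect_gt(d2$wf, d$wf)
    expect_equal(d2$pse, d$pse)
  }
})

test_that("noiseless step data pin the PSE and collapse the slope", {
  # a PSE strictly between two levels makes the data perfectly separable
  sch <- make_schedule(reps = 4, seed = 2)
  tr <- simulate_responses(observer_params(0, 16.5), sch, seed = 3)
  fit <- fit_psychometric(tr)
  expect_lt(abs(fit$pse - 16.5), 2)  # within one level step
  expect_equal(fit$sigma_log, fit_options()$sigma_bounds[1], tolerance = 1e-6)
  expect_false(fit$converged)
})

test_that("the MLE matches a brute-force grid search over the likelihood", {
  tr <- simulate_responses(observer_params(0.15, 16),
                           make_schedule(reps = 100, seed = 10), seed = 11)
  fit <- fit_psychometric(tr)
  cnt <- level_counts(tr)
  opts <- fit_options()
  mus <- seq(opts$mu_bounds[1], opts$mu_bounds[2], length.out = 400)
  sigmas <- seq(opts$sigma_bounds[1], opts$sigma_bounds[2], length.out = 400)
  nll <- outer(mus, sigmas, Vectorize(function(m, s) oracle_psy_nll(m, s, cnt$lev, cnt$k, cnt$n)))
  best <- arrayInd(which.min(nll), dim(nll))
  expect_lt(abs(fit$mu_log - mus[best[1]]), diff(mus[1:2]))
  expect_lt(abs(fit$sigma_log - sigmas[best[2]]), diff(sigmas[1:2]))
  # and the optimizer's likelihood is at least as good as the lattice's
  expect_lte(oracle_psy_nll(fit$mu_log, fit$sigma_log, cnt$lev, cnt$k, cnt$n),
             min(nll) + 1e-6)
})

test_that("degenerate and insufficient data raise classed errors", {
  sch <- make_schedule(reps = 2, seed = 4)
  all_many <- simulate_responses(observer_params(0.1, 1e-6), sch, seed = 5)
  expect_error(fit_psychometric(all_many), class = "numsense_degenerate_fit")
  one_level <- data.frame(numerosity = rep(16, 8), is_anchor = FALSE,
                          response_many = rep(c(TRUE, FALSE), 4))
  expect_error(fit_psychometric(one_level), class = "numsense_invalid_input")
})

test_that("the fitted likelihood dominates the generating parameters", {
  # MLE optimality, sampled: the data log-likelihood at the estimate must
  # beat the truth in nearly every replicate
  wins <- vapply(1:60, function(s) {
    wf <- runif(1, 0.08, 0.4); pse <- runif(1, 12, 20)
    tr <- simulate_responses(observer_params(wf, pse),
                             make_schedule(reps = 4, seed = 300 + s), seed = s)
    fit <- fit_psychometric(tr)
    cnt <- level_counts(tr)
    true_nll <- oracle_psy_nll(log10(pse), log10(1 + wf) / qnorm(0.75),
                               cnt$lev, cnt$k, cnt$n)
    (-fit$loglik) <= true_nll + 1e-9
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("pooling trials across identical participants leaves the fit unchanged", {
  co <- generate_cohort(cohort_config(n_per_group = 2, seed = 31,
                                      sex_counts = list(ADHD = c(M = 1, F = 1),
                                                        control = c(M = 1, F = 1)),
                                      irp_missing = c(ADHD = 0L, control = 0L),
                                      missing_pattern = list(
                                        ADHD = setNames(rep(1L, 6), math_tasks()),
                                        control = setNames(rep(0L, 6), math_tasks()))))
  one_id <- co$participants$id[1]
  solo <- co
  solo$participants <- co$participants[1, , drop = FALSE]
  solo$trials <- co$trials[co$trials$id == one_id, , drop = FALSE]
  f_solo <- fit_group_aggregate(solo, "ADHD")
  f_ind <- fit_psychometric(solo$trials)
  expect_equal(f_solo, f_ind)
  # duplicating the same participant doubles every count: same argmax
  dup <- solo
  t2 <- solo$trials; t2$id <- "A99"
  dup$participants <- rbind(solo$participants, transform(solo$participants, id = "A99"))
  dup$trials <- rbind(solo$trials, t2)
  f_dup <- fit_group_aggregate(dup, "ADHD")
  expect_equal(f_dup$mu_log, f_ind$mu_log, tolerance = 1e-4)
  expect_equal(f_dup$sigma_log, f_ind$sigma_log, tolerance = 1e-4)
})

test_that("a pooled group fit recovers shared observer parameters", {
  cfg <- cohort_config(n_per_group = 10, seed = 37,
                       wf_mean = c(ADHD = 0.2, control = 0.2),
                       wf_sd = c(ADHD = 1e-4, control = 1e-4),
                       pse_mean = c(ADHD = 15, control = 15),
                       pse_sd = c(ADHD = 1e-4, control = 1e-4),
                       sex_counts = list(ADHD = c(M = 5, F = 5),
                                         control = c(M = 5, F = 5)),
                       missing_pattern = list(
                         ADHD = setNames(rep(1L, 6), math_tasks()),
                         control = setNames(rep(0L, 6), math_tasks())))
  co <- generate_cohort(cfg)
  agg <- fit_group_aggregate(co, "ADHD")
  expect_lt(abs(agg$wf - 0.2), 0.05)
  expect_lt(abs(agg$pse - 15), 0.8)
})

test_that("per-participant fits are exported with the documented columns", {
  co <- generate_cohort(cohort_config(seed = 41))
  fits <- fit_cohort(co)
  expect_equal(nrow(fits), 40)
  expect_identical(names(fits), c("id", "group", "mu_log", "sigma_log", "pse",
                                  "jnd_log", "wf", "n_trials", "loglik", "converged"))
  expect_true(all(fits$n_trials == 44))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_fits(fits, tmp)
  expect_equal(read.csv(tmp)$wf, fits$wf)
})
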