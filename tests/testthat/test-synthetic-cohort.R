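test_that("the response model hits its defining probabilities", {
  # at the PSE the two categories are equally likely
  expect_equal(p_many(16, wf = 0.2, pse = 16), 0.5)
  # the Weber fraction is defined so that p(many) = 0.75 at pse * (1 + wf)
  for (wf in c(0.05, 0.15, 0.3, 0.45)) {
    expect_equal(p_many(16 * (1 + wf), wf = wf, pse = 16), 0.75, tolerance = 1e-9)
  }
  # noiseless limit: a step function around the PSE
  expect_equal(p_many(c(8, 15.9, 16, 16.1, 32), wf = 0, pse = 16),
               c(0, 0, 0.5, 1, 1))
})

test_that("simulated response frequencies match the closed-form probability", {
  # p(many) at N = 32 for wf = 0.15, pse = 16, evaluated independently
  p_expected <- pnorm(log10(2) * qnorm(0.75) / log10(1.15))
  obs <- observer_params(0.15, 16)
  sch <- make_schedule(make_levels(32, 64, 2), reps = 5000, seed = 1)
  tr <- simulate_responses(obs, sch, seed = 42)
  hits <- tr$response_many[!tr$is_anchor & tr$numerosity == 32]
  se <- sqrt(p_expected * (1 - p_expected) / length(hits))
  expect_lt(abs(mean(hits) - p_expected), 3 * se)
})

test_that("p(many) is non-decreasing in numerosity for any observer", {
  set.seed(31)
  for (i in 1:25) {
    wf <- runif(1, 0, 0.6); pse <- runif(1, 10, 22); lapse <- runif(1, 0, 0.3)
    p <- p_many(seq(4, 64, by = 0.5), wf, pse, lapse)
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("anchor trials never carry responses and determinism holds", {
  obs <- observer_params(0.2, 15)
  sch <- make_schedule(seed = 9)
  t1 <- simulate_responses(obs, sch, seed = 5)
  t2 <- simulate_responses(obs, sch, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(is.na(t1$response_many[t1$is_anchor])))
  expect_true(all(!is.na(t1$response_many[!t1$is_anchor])))
})

test_that("cohorts reproduce the configured composition exactly", {
  co <- generate_cohort(cohort_config(seed = 17), with_trials = FALSE)
  pp <- co$participants
  expect_equal(unname(table(pp$group)[c("ADHD", "control")]), c(20L, 20L),
               ignore_attr = TRUE)
  expect_equal(sum(pp$sex == "M" & pp$group == "ADHD"), 14)
  expect_equal(sum(pp$sex == "F" & pp$group == "control"), 11)
  expect_true(all(pp$age_yr >= 8 & pp$age_yr <= 16))
  expect_true(all(pp$wf_true >= 0.01))
  # missing counts are configuration, not sampling: identical across seeds
  for (seed in c(2, 3, 4)) {
    ppk <- generate_cohort(cohort_config(seed = seed), with_trials = FALSE)$participants
    for (g in c("ADHD", "control")) {
      got <- vapply(math_tasks(), function(t) sum(is.na(ppk[[t]][ppk$group == g])), integer(1))
      expect_identical(unname(got), unname(default_missing_pattern()[[g]]))
    }
  }
  # one clinical participant misses the whole battery
  all_missing <- rowSums(is.na(pp[pp$group == "ADHD", math_tasks()])) == 6
  expect_equal(sum(all_missing), 1)
  # clinical scores only in the clinical group
  expect_true(all(is.na(pp$cprs[pp$group == "control"])))
  expect_true(all(!is.na(pp$cprs[pp$group == "ADHD"])))
})

test_that("cohort generation is bit-reproducible and respects n = 0", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  expect_identical(a$participants, b$participants)
  expect_identical(a$trials, b$trials)
  empty <- generate_cohort(cohort_config(n_per_group = 0), with_trials = FALSE)
  expect_equal(nrow(empty$participants), 0)
})

test_that("replicate cohorts recover the configured Weber fraction moments", {
  wf <- unlist(lapply(1:200, function(s) {
    pp <- generate_cohort(cohort_config(seed = 1000 + s), with_trials = FALSE)$participants
    pp$wf_true[pp$group == "ADHD"]
  }))
  se <- sd(wf) / sqrt(length(wf))
  expect_lt(abs(mean(wf) - 0.177), 3 * se)
  expect_equal(sd(wf), 0.09, tolerance = 0.05)
})

test_that("cohort CSV round trip is exact, including missing cells", {
  tmp <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(seed = 23))
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$participants, co$participants)
  expect_equal(back$trials, co$trials)
  # a missing score stays missing, not zero
  i_na <- which(is.na(co$participants$counting))[1]
  expect_true(is.na(back$participants$counting[i_na]))
})

test_that("malformed cohort files are rejected with row numbers", {
  tmp <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(seed = 29))
  co$trials$response_many[co$trials$is_anchor][1] <- TRUE
  write_cohort(co, tmp)
  expect_error(read_cohort(tmp), "row", class = "numsense_parse_error")

  tmp2 <- withr::local_tempdir()
  co2 <- generate_cohort(cohort_config(seed = 29), with_trials = FALSE)
  co2$participants$group[3] <- "patients"
  write_cohort(co2, tmp2)
  expect_error(read_cohort(tmp2), "row", class = "numsense_parse_error")

  tmp3 <- withr::local_tempdir()
  co3 <- generate_cohort(cohort_config(seed = 29), with_trials = FALSE)
  co3$participants$id[2] <- co3$participants$id[1]
  write_cohort(co3, tmp3)
  expect_error(read_cohort(tmp3), class = "numsense_parse_error")
})

test_that("infeasible configurations are rejected", {
  bad <- default_missing_pattern(); bad$ADHD["counting"] <- 25L
  expect_error(cohort_config(missing_pattern = bad), class = "numsense_invalid_config")
  expect_error(cohort_config(rho_wf_math = 1), class = "numsense_invalid_config")
  expect_error(cohort_config(sex_counts = list(ADHD = c(M = 10, F = 6),
                                               control = c(M = 9, F = 11))),
               class = "numsense_invalid_config")
})
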