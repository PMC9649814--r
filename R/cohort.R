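# Synthetic two-group study cohorts. The generator emulates the statistical
# structure of a clinical numerosity study: two groups of 20 children aged
# 8-16, group-specific Weber fraction and PSE distributions, six math tasks
# with group-specific normative z-score moments, a configured missingness
# pattern (including one clinical-group participant who completed no math
# task), clinical symptom scores for the clinical group, and a latent
# rank-correlation link between numerosity precision and math ability.

#' Default per-task math z-score moments
#'
#' Group-specific means and standard deviations of the six math tasks'
#' age-normative z-scores used by the default cohort configuration.
#' @return A list with elements `mean` and `sd`, each a list with named
#'   per-task vectors for groups `ADHD` and `control`.
#' @export
default_math_moments <- function() {
  tasks <- math_tasks()
  list(
    mean = list(
      ADHD = stats::setNames(c(-0.33, -0.85, -0.28, -0.94, -0.19, -0.58), tasks),
      control = stats::setNames(c(0.78, -0.13, 0.82, 0.12, 0.42, 0.34), tasks)
    ),
    sd = list(
      ADHD = stats::setNames(c(1.18, 1.23, 0.98, 1.07, 1.06, 1.62), tasks),
      control = stats::setNames(c(0.84, 1.28, 0.90, 0.76, 1.17, 0.47), tasks)
    )
  )
}

#' Default per-task missingness pattern
#'
#' Number of absent raw scores per task and group (the complement of the
#' per-task available-case counts 18/18/18/19/19/18 in the clinical group and
#' 20/20/20/19/19/18 among controls).
#' @return A list of named integer vectors for `ADHD` and `control`.
#' @export
default_missing_pattern <- function() {
  tasks <- math_tasks()
  list(ADHD = stats::setNames(c(2L, 2L, 2L, 1L, 1L, 2L), tasks),
       control = stats::setNames(c(0L, 0L, 0L, 1L, 1L, 2L), tasks))
}

#' Configuration of the synthetic cohort generator
#'
#' All generative parameters of a two-group cohort. The defaults reproduce
#' the study conditions the analysis pipeline assumes: 20 participants per
#' group aged 8-16; Weber fractions from a moment-matched truncated normal
#' (floor 0.01) with mean 0.177 (sd 0.09) in the clinical group and 0.143
#' (sd 0.07) in controls; PSEs normal with means 15.63 (2.38) and 14.76
#' (1.97); per-task math z-scores with the moments of
#' [default_math_moments()]; a Gaussian-copula rank correlation of 0.3
#' between numerosity precision (-Wf) and latent math ability; and the
#' missingness pattern of [default_missing_pattern()] with one clinical
#' participant missing every task.
#'
#' @param n_per_group Participants per group.
#' @param age_range_yr Two-element age interval in years.
#' @param age_mean,age_sd Moments of the (truncated) age distribution.
#' @param sex_counts List with named `c(M=, F=)` counts per group; counts
#'   must sum to `n_per_group`.
#' @param wf_mean,wf_sd Named per-group Weber fraction moments (after
#'   truncation at `wf_floor`).
#' @param wf_floor Lower truncation of the Weber fraction distribution.
#' @param pse_mean,pse_sd Named per-group PSE moments (dots).
#' @param math_z_mean,math_z_sd Per-group, per-task z-score moments.
#' @param task_loading Loading of the shared latent math ability in each
#'   task's z-score (0-1); 0.5 reproduces the aggregate-index dispersion
#'   implied by the per-task moments.
#' @param rho_wf_math Latent (Gaussian copula) rank correlation between -Wf
#'   and math ability, `|rho| < 1`.
#' @param missing_pattern Per-group named counts of absent scores per task.
#' @param adhd_all_missing If `TRUE`, one clinical-group participant is
#'   missing all six tasks (the remaining missingness is spread at random).
#' @param irp_mean,irp_sd Per-group moments of the nonverbal-reasoning
#'   z-score (`irp_z`).
#' @param irp_missing Per-group count of participants without `irp_z`.
#' @param lapse Observer lapse rate for simulated trials.
#' @param schedule List with `n_min`, `n_max`, `n_levels`, `reps` defining
#'   the trial schedule used when trials are simulated.
#' @param seed Master seed; everything downstream is deterministic given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 20,
                          age_range_yr = c(8, 16),
                          age_mean = 11.2, age_sd = 2.4,
                          sex_counts = list(ADHD = c(M = 14, F = 6),
                                            control = c(M = 9, F = 11)),
                          wf_mean = c(ADHD = 0.177, control = 0.143),
                          wf_sd = c(ADHD = 0.09, control = 0.07),
                          wf_floor = 0.01,
                          pse_mean = c(ADHD = 15.63, control = 14.76),
                          pse_sd = c(ADHD = 2.38, control = 1.97),
                          math_z_mean = default_math_moments()$mean,
                          math_z_sd = default_math_moments()$sd,
                          task_loading = 0.5,
                          rho_wf_math = 0.3,
                          missing_pattern = default_missing_pattern(),
                          adhd_all_missing = TRUE,
                          irp_mean = c(ADHD = -0.15, control = 0.42),
                          irp_sd = c(ADHD = 0.9, control = 0.95),
                          irp_missing = c(ADHD = 4L, control = 0L),
                          lapse = 0,
                          schedule = list(n_min = 8, n_max = 32, n_levels = 11, reps = 4),
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  if (!is_count(n_per_group)) abort_ns("`n_per_group` must be a nonnegative integer", "numsense_invalid_config")
  if (any(unlist(wf_sd) <= 0) || any(unlist(pse_sd) <= 0) ||
      any(unlist(lapply(math_z_sd, unlist)) <= 0)) {
    abort_ns("all standard deviations must be > 0", "numsense_invalid_config")
  }
  if (abs(rho_wf_math) >= 1) abort_ns("|rho_wf_math| must be < 1", "numsense_invalid_config")
  if (task_loading < 0 || task_loading > 1) abort_ns("`task_loading` must be in [0, 1]", "numsense_invalid_config")
  if (n_per_group > 0) {
    for (g in c("ADHD", "control")) {
      if (sum(sex_counts[[g]]) != n_per_group) {
        abort_ns(sprintf("sex counts for group %s must sum to n_per_group", g), "numsense_invalid_config")
      }
      if (any(missing_pattern[[g]] > n_per_group)) {
        abort_ns("missing counts cannot exceed the group size", "numsense_invalid_config")
      }
      if (irp_missing[[g]] > n_per_group) {
        abort_ns("`irp_missing` cannot exceed the group size", "numsense_invalid_config")
      }
    }
    if (adhd_all_missing && any(missing_pattern$ADHD < 1)) {
      abort_ns("`adhd_all_missing` needs every task's clinical missing count >= 1", "numsense_invalid_config")
    }
  }
  cfg
}

# Mean and sd of a normal(mu, sig) truncated below at `a`.
truncnorm_moments <- function(mu, sig, a) {
  alpha <- (a - mu) / sig
  lam <- stats::dnorm(alpha) / stats::pnorm(alpha, lower.tail = FALSE)
  m <- mu + sig * lam
  v <- sig^2 * (1 + alpha * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

# Pre-truncation (mu, sig) whose truncated-at-`a` distribution has exactly
# the target mean and sd, so configured moments are generator moments.
truncnorm_match <- function(target_mean, target_sd, a) {
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), a)
    (m[["mean"]] - target_mean)^2 + (m[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sig = exp(fit$par[2]))
}

# Quantile function of the truncated normal (lower truncation at `a`).
qtruncnorm <- function(p, mu, sig, a) {
  pa <- stats::pnorm(a, mu, sig)
  stats::qnorm(pa + p * (1 - pa), mu, sig)
}

#' Generate a synthetic two-group cohort
#'
#' Draws a full cohort from a [cohort_config()]: demographics, true observer
#' parameters, per-task raw math scores (obtained by inverting the normative
#' table so their standardization lands on the configured z moments),
#' clinical scores for the clinical group, nonverbal-reasoning z-scores, the
#' configured missingness, and (optionally) per-trial categorization
#' responses simulated from each participant's true psychometric function.
#' Bit-reproducible given `config$seed`; per-task missing counts are fixed by
#' configuration, not sampled.
#'
#' @param config A [cohort_config()].
#' @param with_trials Simulate per-trial responses (default `TRUE`).
#' @param norms Normative table used to invert z-scores into raw scores.
#' @return An object of class `ans_cohort`: a list with `participants` (one
#'   row per participant), `trials` (one row per trial, or `NULL`), and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(), with_trials = TRUE,
                            norms = read_norms()) {
  n <- config$n_per_group
  groups <- c("ADHD", "control")
  if (n == 0L) {
    return(structure(list(participants = empty_participants(), trials = NULL,
                          config = config), class = "ans_cohort"))
  }

  with_seed(config$seed, {
    parts <- list()
    for (g in groups) {
      id <- sprintf("%s%02d", if (g == "ADHD") "A" else "C", seq_len(n))
      sex <- sample(rep(c("M", "F"), config$sex_counts[[g]][c("M", "F")]))

      # truncated-normal ages with the configured moments' parent normal
      age <- numeric(0)
      while (length(age) < n) {
        cand <- stats::rnorm(2 * n, config$age_mean, config$age_sd)
        age <- c(age, cand[cand >= config$age_range_yr[1] & cand <= config$age_range_yr[2]])
      }
      age <- round(age[seq_len(n)], 1)

      # Gaussian copula between -Wf (precision) and latent math ability
      zw <- stats::rnorm(n)
      ability <- config$rho_wf_math * (-zw) +
        sqrt(1 - config$rho_wf_math^2) * stats::rnorm(n)
      par_tn <- truncnorm_match(config$wf_mean[[g]], config$wf_sd[[g]], config$wf_floor)
      wf <- qtruncnorm(stats::pnorm(zw), par_tn[["mu"]], par_tn[["sig"]], config$wf_floor)
      pse <- stats::rnorm(n, config$pse_mean[[g]], config$pse_sd[[g]])

      df <- data.frame(id = id, group = g, age_yr = age, sex = sex,
                       wf_true = wf, pse_true = pse, stringsAsFactors = FALSE)

      lam <- config$task_loading
      for (task in math_tasks()) {
        z <- config$math_z_mean[[g]][[task]] + config$math_z_sd[[g]][[task]] *
          (lam * ability + sqrt(1 - lam^2) * stats::rnorm(n))
        df[[task]] <- vapply(seq_len(n), function(i) {
          raw_from_z(z[i], task, age[i], norms)
        }, numeric(1))
      }

      # missingness: configured counts per task; optionally one clinical
      # participant missing the whole battery
      miss <- config$missing_pattern[[g]]
      pool <- seq_len(n)
      if (g == "ADHD" && config$adhd_all_missing) {
        i_all <- sample(pool, 1)
        for (task in math_tasks()) df[[task]][i_all] <- NA_real_
        miss <- miss - 1L
        pool <- setdiff(pool, i_all)
      }
      for (task in math_tasks()) {
        if (miss[[task]] > 0) {
          i_miss <- sample(pool, miss[[task]])
          df[[task]][i_miss] <- NA_real_
        }
      }

      # clinical symptom scores (clinical group only): CPRS index T-scores,
      # CGI-S severity integers, raw CGAS functioning scores (1-100; the
      # pipeline recodes them into 1-10 severity categories)
      if (g == "ADHD") {
        df$cgi_s <- sample(3:6, n, replace = TRUE, prob = c(0.25, 0.4, 0.25, 0.1))
        df$cgas <- pmin(pmax(round(stats::rnorm(n, 55, 12)), 21), 90)
        df$cprs <- pmin(pmax(round(stats::rnorm(n, 60, 10)), 38), 90)
      } else {
        df$cgi_s <- NA_integer_; df$cgas <- NA_real_; df$cprs <- NA_real_
      }

      df$irp_z <- stats::rnorm(n, config$irp_mean[[g]], config$irp_sd[[g]])
      if (config$irp_missing[[g]] > 0) {
        df$irp_z[sample(seq_len(n), config$irp_missing[[g]])] <- NA_real_
      }
      parts[[g]] <- df
    }
    participants <- do.call(rbind, parts)
    rownames(participants) <- NULL

    trials <- NULL
    if (with_trials) {
      rng <- make_levels(config$schedule$n_min, config$schedule$n_max,
                         config$schedule$n_levels)
      seeds <- sample.int(.Machine$integer.max, 2 * nrow(participants))
      tl <- lapply(seq_len(nrow(participants)), function(i) {
        sched <- make_schedule(rng, reps = config$schedule$reps,
                               seed = seeds[2 * i - 1])
        obs <- observer_params(participants$wf_true[i], participants$pse_true[i],
                               config$lapse)
        tr <- simulate_responses(obs, sched, seed = seeds[2 * i])
        cbind(id = participants$id[i], tr, stringsAsFactors = FALSE)
      })
      trials <- do.call(rbind, tl)
      rownames(trials) <- NULL
    }

    structure(list(participants = participants, trials = trials, config = config),
              class = "ans_cohort")
  })
}

empty_participants <- function() {
  df <- data.frame(id = character(0), group = character(0),
                   age_yr = numeric(0), sex = character(0),
                   wf_true = numeric(0), pse_true = numeric(0),
                   stringsAsFactors = FALSE)
  for (task in math_tasks()) df[[task]] <- numeric(0)
  df$cgi_s <- integer(0); df$cgas <- numeric(0); df$cprs <- numeric(0)
  df$irp_z <- numeric(0)
  df
}

#' @export
print.ans_cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<ans_cohort> %s participants%s\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = " + "),
              if (is.null(x$trials)) "" else sprintf(", %d trials", nrow(x$trials))))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Serializes the participants table to `participants.csv` and, when
#' present, the trials table to `trials.csv` inside `dir`. Missing values
#' are written as empty cells; doubles survive the round trip exactly.
#'
#' @param cohort An `ans_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "ans_cohort")) abort_ns("`cohort` must be an ans_cohort", "numsense_invalid_argument")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_ns(cohort$participants, file.path(dir, "participants.csv"))
  if (!is.null(cohort$trials)) {
    write_csv_ns(cohort$trials, file.path(dir, "trials.csv"))
  }
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Counterpart of [write_cohort()]. Validates group labels, id uniqueness
#' and the trial-table invariants (anchor trials must carry no response);
#' violations raise parse errors naming the offending rows. Works with or
#' without a trials file, so cohorts with precomputed Weber fractions and
#' PSEs (in `wf_true` / `pse_true`) are accepted.
#'
#' @param dir Directory holding `participants.csv` and optionally
#'   `trials.csv`.
#' @return An `ans_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  pp <- read_csv_ns(file.path(dir, "participants.csv"))
  if (!all(c("id", "group") %in% names(pp))) {
    abort_ns("participants.csv must have `id` and `group` columns", "numsense_parse_error")
  }
  bad_grp <- which(!pp$group %in% c("ADHD", "control"))
  if (length(bad_grp)) {
    abort_ns(sprintf("unknown group label in participants.csv row(s) %s",
                     paste(bad_grp, collapse = ", ")), "numsense_parse_error")
  }
  dup <- which(duplicated(pp$id))
  if (length(dup)) {
    abort_ns(sprintf("duplicate participant id in participants.csv row(s) %s",
                     paste(dup, collapse = ", ")), "numsense_parse_error")
  }
  trials <- NULL
  tpath <- file.path(dir, "trials.csv")
  if (file.exists(tpath)) {
    trials <- read_csv_ns(tpath)
    need <- c("id", "trial_index", "numerosity", "is_anchor", "response_many")
    if (!all(need %in% names(trials))) {
      abort_ns(sprintf("trials.csv must have columns: %s", paste(need, collapse = ", ")),
               "numsense_parse_error")
    }
    trials$is_anchor <- as.logical(trials$is_anchor)
    trials$response_many <- as.logical(trials$response_many)
    bad <- which(trials$is_anchor & !is.na(trials$response_many))
    if (length(bad)) {
      abort_ns(sprintf("anchor trial carries a response in trials.csv row(s) %s",
                       paste(bad, collapse = ", ")), "numsense_parse_error")
    }
    orphan <- setdiff(unique(trials$id), pp$id)
    if (length(orphan)) {
      abort_ns(sprintf("trials.csv references unknown participant id(s): %s",
                       paste(orphan, collapse = ", ")), "numsense_parse_error")
    }
  }
  structure(list(participants = pp, trials = trials, config = NULL),
            class = "ans_cohort")
}
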