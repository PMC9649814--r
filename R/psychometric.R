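# Maximum-likelihood psychometric fitting. The proportion of "many"
# responses is modeled as a cumulative Gaussian of log10 numerosity; the 50%
# point gives the PSE, the 50->75% distance (in log10 units) the JND, and
# 10^JND - 1 the Weber fraction. Fitting maximizes the Bernoulli likelihood
# of the raw trials (not least squares on binned proportions) with bounded
# multi-start optimization.

#' Options for psychometric fitting
#'
#' @param sigma_bounds Bounds for the slope parameter (log10 units).
#' @param mu_bounds Bounds for the mean (log10 numerosity); the defaults span
#'   4 to 64 dots, one octave beyond the default stimulus range on each side.
#' @param n_starts Number of optimizer starts (deterministic grid).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(sigma_bounds = c(1e-3, 1),
                        mu_bounds = log10(c(4, 64)),
                        n_starts = 5) {
  if (length(sigma_bounds) != 2 || any(!is.finite(sigma_bounds)) ||
      sigma_bounds[1] >= sigma_bounds[2] || sigma_bounds[1] <= 0) {
    abort_ns("`sigma_bounds` must be finite, positive, ordered", "numsense_invalid_argument")
  }
  if (length(mu_bounds) != 2 || any(!is.finite(mu_bounds)) || mu_bounds[1] >= mu_bounds[2]) {
    abort_ns("`mu_bounds` must be finite and ordered", "numsense_invalid_argument")
  }
  if (!is_count(n_starts, positive = TRUE)) {
    abort_ns("`n_starts` must be a positive integer", "numsense_invalid_argument")
  }
  structure(list(sigma_bounds = sigma_bounds, mu_bounds = mu_bounds,
                 n_starts = as.integer(n_starts)),
            class = "fit_options")
}

#' Derive PSE, JND and Weber fraction from fitted parameters
#'
#' `pse = 10^mu_log`; `jnd_log = qnorm(0.75) * sigma_log` (the 50% to 75%
#' distance of the cumulative Gaussian, in log10 numerosity units);
#' `wf = 10^jnd_log - 1`, which equals `N75/N50 - 1` in dots.
#'
#' @param mu_log Mean of the cumulative Gaussian (log10 numerosity).
#' @param sigma_log Standard deviation (log10 units, `>= 0`).
#' @return A list with `pse`, `jnd_log`, `wf`.
#' @export
derive_indices <- function(mu_log, sigma_log) {
  if (!is_scalar_num(mu_log) || !is_scalar_num(sigma_log) || sigma_log < 0) {
    abort_ns("`mu_log` must be finite and `sigma_log` >= 0", "numsense_invalid_argument")
  }
  jnd_log <- z75 * sigma_log
  list(pse = 10^mu_log, jnd_log = jnd_log, wf = 10^jnd_log - 1)
}

# Collapse raw trials to per-level counts (the sufficient statistic).
aggregate_trials <- function(trials) {
  keep <- !trials$is_anchor & !is.na(trials$response_many)
  tr <- trials[keep, , drop = FALSE]
  if (nrow(tr) == 0L) abort_ns("no scored test trials", "numsense_invalid_input")
  lev <- sort(unique(tr$numerosity))
  k <- vapply(lev, function(l) sum(tr$response_many[tr$numerosity == l]), numeric(1))
  n <- vapply(lev, function(l) sum(tr$numerosity == l), numeric(1))
  list(l10 = log10(lev), k = k, n = n)
}

nll_psy <- function(par, agg) {
  p <- stats::pnorm((agg$l10 - par[1]) / par[2])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(agg$k * log(p) + (agg$n - agg$k) * log1p(-p))
}

#' Fit a cumulative Gaussian psychometric function
#'
#' Maximum-likelihood estimate of the mean and slope of a cumulative Gaussian
#' on log10 numerosity from raw Bernoulli trials. Anchor trials and trials
#' without responses are excluded. Optimization is bounded (L-BFGS-B) from a
#' deterministic grid of starts; ties are broken by higher log-likelihood,
#' then smaller sigma.
#'
#' @param trials Data frame with `numerosity`, `response_many`, `is_anchor`
#'   (as produced by [simulate_responses()] or read from a trials file).
#' @param options A [fit_options()].
#'
#' @return An object of class `psychometric_fit`: `mu_log`, `sigma_log`,
#'   `pse`, `jnd_log`, `wf`, `n_trials`, `loglik`, `converged`. `converged`
#'   is `FALSE` when every start failed or ended on a parameter bound (as in
#'   the noiseless limit, where sigma collapses to its lower bound).
#'
#' @details Requires at least two distinct test numerosities and at least one
#'   response in each category; all-"many" or all-"few" data have no finite
#'   maximum-likelihood estimate and raise `numsense_degenerate_fit`.
#' @export
fit_psychometric <- function(trials, options = fit_options()) {
  agg <- aggregate_trials(trials)
  if (length(agg$l10) < 2L) {
    abort_ns("need responses at >= 2 distinct numerosities", "numsense_invalid_input")
  }
  tot_k <- sum(agg$k); tot_n <- sum(agg$n)
  if (tot_k == 0 || tot_k == tot_n) {
    abort_ns("all responses identical; psychometric fit is degenerate", "numsense_degenerate_fit")
  }

  lo <- c(options$mu_bounds[1], options$sigma_bounds[1])
  hi <- c(options$mu_bounds[2], options$sigma_bounds[2])

  # Empirical 50% crossing as a starting mean; fall back to the level closest
  # to 0.5 proportion, then to the range midpoint.
  prop <- agg$k / agg$n
  mu_emp <- tryCatch(
    stats::approx(prop, agg$l10, xout = 0.5, ties = mean)$y,
    warning = function(w) NA_real_, error = function(e) NA_real_
  )
  if (is.na(mu_emp)) mu_emp <- agg$l10[which.min(abs(prop - 0.5))]
  mu_emp <- min(max(mu_emp, lo[1]), hi[1])
  mu_mid <- mean(range(agg$l10))
  starts <- rbind(
    c(mu_emp, 0.05), c(mu_emp, 0.15), c(mu_mid, 0.08),
    c(mu_mid, 0.25), c(mu_emp, 0.45)
  )
  starts <- starts[seq_len(min(nrow(starts), options$n_starts)), , drop = FALSE]
  starts[, 2] <- pmin(pmax(starts[, 2], lo[2]), hi[2])

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(starts[i, ], nll_psy, agg = agg, method = "L-BFGS-B",
                   lower = lo, upper = hi),
      error = function(e) NULL
    )
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) abort_ns("all optimizer starts failed", "numsense_degenerate_fit")

  vals <- vapply(runs, function(r) r$value, numeric(1))
  sigs <- vapply(runs, function(r) r$par[2], numeric(1))
  best <- runs[[order(vals, sigs)[1]]]

  tol <- 1e-6
  interior <- function(r) {
    all(r$par > lo + tol) && all(r$par < hi - tol)
  }
  ok <- vapply(runs, function(r) r$convergence == 0 && interior(r), logical(1))

  idx <- derive_indices(best$par[1], best$par[2])
  structure(
    list(mu_log = unname(best$par[1]), sigma_log = unname(best$par[2]),
         pse = idx$pse, jnd_log = idx$jnd_log, wf = idx$wf,
         n_trials = as.integer(tot_n), loglik = -best$value,
         converged = any(ok)),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE = %.2f dots, Wf = %.3f (mu = %.4f, sigma = %.4f, n = %d, logLik = %.2f%s)\n",
              x$pse, x$wf, x$mu_log, x$sigma_log, x$n_trials, x$loglik,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Pooled (aggregate) psychometric fit for a group
#'
#' Pools every scored test trial across the participants of one group and
#' fits a single psychometric function, as in aggregate group curves.
#'
#' @param cohort A cohort object (see [generate_cohort()] / [read_cohort()])
#'   whose `trials` component is non-`NULL`.
#' @param group Group label to pool (e.g. `"ADHD"` or `"control"`).
#' @param options A [fit_options()].
#' @return A `psychometric_fit`.
#' @export
fit_group_aggregate <- function(cohort, group, options = fit_options()) {
  if (is.null(cohort$trials)) abort_ns("cohort has no trial data", "numsense_invalid_input")
  ids <- cohort$participants$id[cohort$participants$group == group]
  if (length(ids) == 0L) abort_ns(sprintf("no participants in group '%s'", group), "numsense_invalid_input")
  tr <- cohort$trials[cohort$trials$id %in% ids, , drop = FALSE]
  fit_psychometric(tr, options)
}

#' Fit every participant of a cohort
#'
#' @param cohort A cohort object with per-trial data.
#' @param options A [fit_options()].
#' @return A data frame with one row per participant holding the fitted
#'   parameters and derived indices (`id`, `group`, `mu_log`, `sigma_log`,
#'   `pse`, `jnd_log`, `wf`, `n_trials`, `loglik`, `converged`). A
#'   degenerate fit aborts with an error naming the participant.
#' @export
fit_cohort <- function(cohort, options = fit_options()) {
  if (is.null(cohort$trials)) abort_ns("cohort has no trial data", "numsense_invalid_input")
  pp <- cohort$participants
  rows <- lapply(seq_len(nrow(pp)), function(i) {
    id <- pp$id[i]
    tr <- cohort$trials[cohort$trials$id == id, , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    f <- tryCatch(fit_psychometric(tr, options), numsense_error = function(e) {
      abort_ns(sprintf("participant %s: %s", id, conditionMessage(e)), class(e)[1])
    })
    data.frame(id = id, group = pp$group[i], mu_log = f$mu_log,
               sigma_log = f$sigma_log, pse = f$pse, jnd_log = f$jnd_log,
               wf = f$wf, n_trials = f$n_trials, loglik = f$loglik,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Write per-participant fits to CSV
#'
#' @param fits Data frame from [fit_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) write_csv_ns(fits, path)
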