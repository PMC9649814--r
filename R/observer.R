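# Synthetic observers for the "many"/"few" categorization task. An observer
# is a cumulative Gaussian on log10 numerosity: the Weber fraction fixes the
# slope through sigma = log10(1 + wf) / z75, so that the probability of
# responding "many" reaches 75% exactly at pse * (1 + wf).

#' Generative parameters of a synthetic observer
#'
#' @param wf_true True Weber fraction (dimensionless, `>= 0`; 0 is the
#'   noiseless step-function limit).
#' @param pse_true True point of subjective equality, in dots (`> 0`).
#' @param lapse Lapse rate in `[0, 0.5]`: the probability of a stimulus
#'   independent random response, split evenly between the two categories.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(wf_true, pse_true, lapse = 0) {
  if (!is_scalar_num(wf_true) || wf_true < 0) {
    abort_ns("`wf_true` must be a finite number >= 0", "numsense_invalid_argument")
  }
  if (!is_scalar_num(pse_true) || pse_true <= 0) {
    abort_ns("`pse_true` must be positive", "numsense_invalid_argument")
  }
  if (!is_scalar_num(lapse) || lapse < 0 || lapse > 0.5) {
    abort_ns("`lapse` must be in [0, 0.5]", "numsense_invalid_argument")
  }
  structure(list(wf_true = wf_true, pse_true = pse_true, lapse = lapse),
            class = "observer_params")
}

#' Probability of a "many" response
#'
#' The psychometric model: `p = lapse/2 + (1 - lapse) * Phi((log10 N -
#' log10 pse) / sigma)` with `sigma = log10(1 + wf) / z75`,
#' `z75 = qnorm(0.75)`. At `N = pse` the probability is 1/2 (plus nothing
#' from the symmetric lapse); at `N = pse * (1 + wf)` it is 3/4 when
#' `lapse = 0`. A Weber fraction of 0 gives the deterministic step function
#' (1/2 exactly at the PSE).
#'
#' @param numerosity Stimulus numerosity (vectorized).
#' @param wf Weber fraction.
#' @param pse Point of subjective equality in dots.
#' @param lapse Lapse rate.
#' @return Vector of probabilities.
#' @export
p_many <- function(numerosity, wf, pse, lapse = 0) {
  if (any(numerosity <= 0)) abort_ns("`numerosity` must be positive", "numsense_invalid_argument")
  if (wf == 0) {
    core <- ifelse(numerosity > pse, 1, ifelse(numerosity < pse, 0, 0.5))
  } else {
    sigma <- log10(1 + wf) / z75
    core <- stats::pnorm((log10(numerosity) - log10(pse)) / sigma)
  }
  lapse / 2 + (1 - lapse) * core
}

#' Simulate categorization responses for one observer
#'
#' Draws a Bernoulli "many" response for every test trial of a schedule from
#' the observer's psychometric function. Anchor trials are emitted with a
#' missing response (none is collected during anchoring).
#'
#' @param observer An [observer_params()].
#' @param schedule A [make_schedule()] trial schedule.
#' @param seed Integer seed; responses are deterministic given the seed.
#' @return A data frame with `trial_index`, `numerosity`, `is_anchor` and
#'   logical `response_many` (`NA` on anchor trials).
#' @export
simulate_responses <- function(observer, schedule, seed = 1L) {
  if (!inherits(observer, "observer_params")) {
    abort_ns("`observer` must be observer_params", "numsense_invalid_argument")
  }
  if (!inherits(schedule, "trial_schedule")) {
    abort_ns("`schedule` must be a trial_schedule", "numsense_invalid_argument")
  }
  tr <- schedule$trials
  test <- !tr$is_anchor
  p <- p_many(tr$numerosity[test], observer$wf_true, observer$pse_true, observer$lapse)
  resp <- rep(NA, nrow(tr))
  resp[test] <- with_seed(seed, stats::runif(sum(test)) < p)
  tr$response_many <- as.logical(resp)
  tr
}
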