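---
title: "Measuring the visual number sense and its relation to math ability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the visual number sense and its relation to math ability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numsense)
```

`numsense` implements the computational chain of a two-group clinical
psychophysics study: visual numerosity perception measured with a brief
"many"/"few" categorization task, symbolic math ability measured with an
age-normed six-task battery, and a default-Bayesian comparison layer that
asks whether a clinical group's math deficit can be explained by its number
sense. This vignette documents the models, the choices behind every tunable
parameter, and what the synthetic-cohort machinery does and does not tell
you about real data.

## The psychometric model

On each test trial an observer sees `N` dots for 500 ms and categorizes the
set as "many" or "few". The probability of "many" is modeled as a cumulative
Gaussian in log10 numerosity,

$$ p(\text{many} \mid N) = \Phi\!\left(\frac{\log_{10} N - \mu}{\sigma}\right), $$

a standard description of magnitude discrimination under Weber's law (noise
proportional to magnitude becomes additive on a log axis). Three indices
derive from the fit:

* **PSE** (point of subjective equality) $= 10^{\mu}$ — the numerosity at
  which both responses are equally likely; an accuracy/bias index.
* **JND** $= z_{75}\,\sigma$ with $z_{75} = \Phi^{-1}(0.75) \approx 0.6745$ —
  the 50%-to-75% distance of the curve, in log10 units.
* **Weber fraction** $W\!f = 10^{\mathrm{JND}} - 1$, equivalently
  $N_{75}/N_{50} - 1$: the proportional increase in numerosity needed to move
  from guessing to 75% "many". Lower values mean higher precision.

Taking the JND literally as the 50–75% distance (rather than as $\sigma$
itself, another common convention) is forced by dimensional coherence: only a
log-unit JND makes $10^{\mathrm{JND}} - 1$ a meaningful ratio-minus-one. The
two conventions differ by the constant factor $z_{75}$, so rank-based
analyses are unaffected by the choice; absolute Weber fractions would scale.

### Fitting

`fit_psychometric()` maximizes the Bernoulli likelihood of the raw trials
(collapsed to per-level counts, the sufficient statistic) rather than
least-squares on binned proportions; with 4 repetitions per level the
binomial heteroscedasticity makes least squares noticeably less efficient.
Optimization is bounded L-BFGS-B from five deterministic starts
(empirical-crossing and midpoint means crossed with shallow-to-steep
slopes), with ties broken by log-likelihood and then by the smaller
$\sigma$. Bounds are $\mu \in [\log_{10} 4, \log_{10} 64]$ (an octave beyond
the stimulus range on each side) and $\sigma \in [10^{-3}, 1]$; perfectly
separable data collapse onto the lower $\sigma$ bound and are flagged
`converged = FALSE` rather than hidden. All-"many" or all-"few" data have no
finite MLE and raise a classed error instead of returning a boundary
estimate.

At the session budget of the categorization task (44 scored trials) the Weber
fraction estimator is noisy and slightly conservative — the package's
recovery tests put the median estimate for a $W\!f = 0.30$ observer within
±0.05 of the truth and the population-level bias within ±0.02 at 40
repetitions per level — which is why group comparisons, not individual
diagnostics, are the intended use.

## The stimulus design

`make_levels()` spaces numerosities geometrically (log-uniformly), matching
the log-Gaussian response model; the default 8–32 ladder in 11 steps rounds
to 8, 9, 11, 12, 14, 16, 18, 21, 24, 28, 32 with geometric mean 16.
Rounding is half-away-from-zero, the convention that reproduces this printed
ladder (10.56 → 11, 27.86 → 28); base R's round-half-even would break it.
`make_schedule()` prepends four unscored anchor trials showing the two
extremes twice each. The order is fixed as max, min, max, min: alternation
exposes both category prototypes immediately, and a deterministic order
keeps schedules reproducible. Anchors carry no responses and are excluded
from every fit. `place_dots()` rejection-samples dot centers uniformly in
the field (10,000 tries per dot; at the default density of at most 32 dots
of 0.25° in a 12° field, rejections are rare) and balances white/black
polarity to within one dot. Dot positions are re-randomized independently
per trial; coordinates are degrees of visual angle with no pixel rendering.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis layer
assumes, so the full pipeline runs and can be tested without any data
deposit. Its defaults are the study conditions, not free dials:

* Two groups of 20, ages 8–16 (truncated normal, mean 11.2, sd 2.4 — the
  reported mean age with a dispersion chosen to fill the range plausibly);
  sex fixed at 14M/6F (clinical) and 9M/11F (control).
* Weber fractions from a normal truncated below at 0.01, with the
  *post-truncation* mean and sd moment-matched to the configured 0.177
  (0.09) and 0.143 (0.07). Moment matching (solved numerically at
  generation time) keeps the configured values exact generator moments; the
  truncation also produces the positive skewness such samples show.
* PSEs normal: 15.63 (2.38) and 14.76 (1.97) dots.
* Per-task math z-scores with the configured group moments. Each task score
  is $z_{t} = m_{g,t} + s_{g,t}(\lambda a + \sqrt{1-\lambda^2}\,
  \varepsilon_t)$, where $a$ is a latent per-child math ability. The task
  loading $\lambda = 0.5$ is fixed by the dispersion of the aggregate index
  implied by the per-task moments (aggregate sd ≈ 0.71/0.58 against task sds
  near 1 requires $\lambda^2 \approx 0.22\!-\!0.29$); it is the one generator
  constant derived from a reported quantity rather than set directly.
* A Gaussian copula ties $-W\!f$ to the latent ability at rank correlation
  0.3, giving the Kendall correlation stage a known positive
  precision–math link to detect.
* Missingness is configuration, not sampling: the per-task counts of absent
  scores (2/2/2/1/1/2 clinical, 0/0/0/1/1/2 control) are applied exactly,
  with one clinical participant missing the entire battery. Which
  participants are affected is the only random part.
* Clinical scores for the clinical group only: CPRS indexes as T-scores
  (normal 60, 10), CGI-S severities 3–6 (the enrolled range for a clinical
  sample), and CGAS as raw 1–100 functioning scores. The generator emits raw
  CGAS scores and the pipeline recodes them into 1–10 severity categories,
  because the recoding is an analysis step, not a property of the
  instrument. None of the clinical scores is generatively linked to
  numerosity, so their correlations with it are null by construction.
* A nonverbal-reasoning z-score (`irp_z`; means −0.15/0.42, sds 0.9/0.95)
  with 4 clinical-group values missing, mirroring participants whose IQ was
  assessed externally.

Raw math scores are produced by inverting the normative table, so the
pipeline's own standardization reproduces the configured z-scores exactly.
The packaged table (`synthetic_norms.csv`) is synthetic — real battery norms
are proprietary — with one-year bands from 8 to 16 and raw-score means
increasing with age.

What the generator does **not** emulate: item-level task structure,
practice/fatigue effects, response times, any direct effect of clinical
severity on performance, and non-Gaussian tails beyond what truncation
induces. Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers the statistical structure it assumes, not that real
populations have that structure.

## The Bayesian layer

All tests report log10 Bayes factors (LBF) of the alternative over the
null; |LBF| > 0.5 is read as substantial evidence, > 1 strong, > 2
definitive, with strict inequalities (an LBF of exactly 0.5 is
inconclusive). Default priors mirror the defaults of mainstream GUI
Bayesian software so that results are comparable to published analyses that
used them; every scale is exposed in configuration.

* **Two-sample t-test** (`lbf_ttest_two_sample`): JZS setup, Cauchy(0,
  0.707) on the standardized difference. Implemented as the noncentral-t
  likelihood integrated over the prior; the test suite checks it against the
  mathematically equivalent but numerically different g-mixture quadrature
  to |Δ| < 10⁻³.
* **Rank-based two-sample test** (`lbf_mannwhitney`): latent-normal data
  augmentation with a seeded Gibbs sampler and a Savage–Dickey density
  ratio at 0 (Gaussian kernel estimate over the posterior draws). No
  analytic form exists; the function reports a Monte Carlo standard error
  (8-batch) and a split-half diagnostic instead of pretending to be exact.
  On normal data it tracks the parametric test closely but not exactly —
  ranks discard the scale information — so cross-method agreement is tested
  within 0.15 log10 units plus Monte Carlo error, a band the observed
  systematic difference sits well inside.
* **Correlations**: `lbf_pearson` uses the exact sampling density of the
  sample correlation (Gauss hypergeometric evaluated by series; the series
  is benign here because its third parameter grows with n) under a
  stretched-beta prior of width 1 (uniform). `lbf_kendall` uses the
  asymptotic normal likelihood of tau-b with variance `2(2n+5)/(9n(n-1))`
  and the same prior family — the standard default-Bayes construction for
  rank correlations. `kendall_tau()` provides brute-force pair counting as
  a transparent cross-check.
* **ANCOVA inclusion** (`lbf_ancova_inclusion`): every additive subset of
  {group, covariates} is a model; each model gets a single-g JZS prior
  (inverse-gamma(1/2, 1/2) mixing, so each standardized effect is
  marginally Cauchy) with scale 0.5 on the ±1/2-coded group contrast and
  0.354 on standardized covariates, and its marginal likelihood is computed
  by one-dimensional quadrature over g. The inclusion BF of a term averages
  model evidence with and without it under equal prior model probabilities;
  for additive spaces the "across all" and "matched models" definitions
  coincide, which is why the `method` argument changes nothing here. With
  only the group term the construction reduces exactly to the JZS t-test —
  a reduction the tests verify against an independent quadrature.
  Covariates are standardized internally; raw-scale covariates can be kept
  by pre-scaling, but standardization is the default because the Cauchy
  scale is meant per SD.
* **Contingency tables** (`lbf_contingency_2x2`): Gunel–Dickey Bayes
  factors with Dirichlet(1) priors, closed-form in gamma functions. The
  default sampling scheme is independent-multinomial with group sizes
  fixed, which matches how a two-group study is actually sampled; joint
  multinomial and hypergeometric variants are provided because published
  analyses do not always say which was used. `lbf_multinomial_test` covers
  the one-sample test against fixed proportions.
* **Power** (`required_n_per_group`): exact noncentral-t power, returning
  the smallest integer n reaching the target; d = 1.2 at α = 0.05 and power
  0.95 gives 20 per group, the design size of a two-group study of this
  kind.

Descriptives use the bias-corrected G1 skewness and G2 excess kurtosis —
the conventions of the GUI software whose tables such studies print — and
the normality gate is a Shapiro–Wilk test per group at α = 0.05, switching
the comparison to the rank-based test when either group rejects. The gate's
W statistics and p values are logged in the report so every test selection
is auditable.

## The pipeline

`run_study()` chains the stages in the order a study report presents them:
cohort acquisition (simulated or from CSV), per-participant psychometric
fits (participants supplied with precomputed Weber fractions and PSEs but no
trials are passed through unchanged), math standardization and the
aggregate index (mean of available z-scores, requiring at least 4 of 6
tasks — the threshold that retains a participant who completed four),
demographic checks, normality-gated group comparisons per measure, Kendall
correlations between Weber fraction and the math aggregate within each
group, ANCOVA inclusion BFs, and clinical correlations within the clinical
group. The ANCOVA stage re-analyzes the measures whose group comparison
crossed the *strong* evidence bar (LBF > 1) plus the aggregate, once with
the Weber fraction as the only covariate and once with Weber fraction,
nonverbal reasoning, age and sex together. Missing data are left missing
and cases are excluded per dependent variable; group-mean imputation
(`impute_group_mean`, which provably preserves group means) is available as
a sensitivity analysis via `impute: true`.

Everything is deterministic given the master seed: sub-seeds are derived
once, the Gibbs sampler is seeded per comparison, and the JSON report
contains no timestamps, so identical configurations produce byte-identical
reports.

## Numerical choices and degenerate inputs

* Quadratures target relative tolerance 10⁻¹⁰, with peaked noncentral-t
  integrands split around their mode so adaptive quadrature cannot step
  over them.
* Gibbs truncated-normal draws use inverse-CDF sampling with a far-tail
  guard that pins numerically empty intervals to the nearest feasible
  endpoint.
* Perfectly collinear correlation data return LBF = ∞ (the marginal
  likelihood genuinely diverges) rather than a large arbitrary number;
  degenerate variance, all-tied ranks, unknown tasks, uncovered ages,
  infeasible dot packings and rank-deficient designs all raise classed
  errors (`numsense_degenerate`, `numsense_no_norm`, ...) so callers can
  distinguish data problems from bugs.
* CSV round trips render doubles with 17 significant digits, making
  write-then-read exact.

## Problem sizes used by the test suite

The packaged tests run the recovery study at 200 observers × 440 trials
plus 500 replicates of the 44-trial session; oracle comparisons at 20
seeded datasets per method against 10⁵-point trapezoid rules; the
headline two-group reproduction at 50 replicate cohorts with full
per-participant fitting; null-calibration of the t-test at 400 simulated
null datasets; and Gibbs chains of 1,500–3,000 kept draws. These sizes were
chosen to keep Monte Carlo error comfortably below the tested tolerances
while keeping the default check quick on a laptop.

## Known limitations

* The rank-based Bayes factor is simulation-based; its Monte Carlo error is
  reported, and analyses that need exactness should use the parametric test
  or more draws.
* The Kendall Bayes factor rests on the asymptotic normality of tau; below
  roughly n = 8 an enumeration-based likelihood would be preferable.
* The ANCOVA uses one shared g per model rather than one per term class;
  with a single factor and a handful of covariates the difference is
  small, but it is a modeling choice, not an approximation error.
* Weber-fraction estimates at 44 trials are noisy; the pipeline treats them
  as group-level measures, and per-participant values should not be read
  diagnostically.
* The synthetic normative table is a stand-in with the right shape, not
  real norms; z-scores from it are internally consistent but not clinically
  interpretable.
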