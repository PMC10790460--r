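---
title: "Measuring composite equity in childhood immunization coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring composite equity in childhood immunization coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxequity)
```

## The problem

Wealth-ranked concentration indices answer one question: are vaccinated
children concentrated among the rich? But household wealth is only one of the
circumstances a child cannot choose. A girl in a rural district born to a
mother without schooling may miss her third DPT dose for reasons that have
nothing to do with her household's assets. This package implements a
*composite* equity assessment: children are ranked by the coverage they are
*predicted* to attain given all the circumstances society deems illegitimate
drivers of vaccination — and the classic concentration-index machinery is run
against that ranking instead of wealth.

## The model

### Direct-unfairness ranking

For each binary outcome $y$ (receipt of a specific dose, zero-dose status,
fully-immunized-for-age, complete schedule) we fit a logistic regression

$$\operatorname{logit} P(y_i = 1) = \beta_0 + \beta_f^\top x_{f,i} +
  \beta_u^\top x_{u,i}$$

where $x_f$ are *fair* sources of variation — the child's age in months and,
for dose outcomes, an indicator that the dose is not yet due ("underage") —
and $x_u$ are *unfair* sources: region of residence, urban/rural setting,
maternal education, household socioeconomic quintile, the child's sex and
insurance coverage. Each unfair covariate has a declared *most privileged*
level which serves as the regression reference, so every fitted log-odds
measures disadvantage relative to the most privileged situation. The fitted
probability $\hat{p}_i$ is the direct-unfairness index, and its weighted
fractional (midpoint CDF) rank $F_i$ the ranking variable.

One ranking model is fitted per outcome (the zero-dose ranking is the
predicted zero-dose risk, and so on), because each outcome's published index
is specific to that outcome. An alternative single shared ranking would be
easy to add but would not reproduce outcome-specific reporting.

### Equity metrics

With weighted mean coverage $\mu$ and survey weights $w_i$:

* **Wagstaff concentration index** $CI_W = \frac{2}{\mu}
  \operatorname{Cov}_w(y, F)$, computed with the *population*-normalized
  weighted covariance — the CDF construction of $F$ presumes population
  weighting, and only then does $CI_W$ equal twice the area between the
  concentration curve and the diagonal exactly (the package asserts this
  identity to $10^{-6}$ on every fixture).
* **Erreygers correction** $CI_E = 4 \mu \, CI_W$, the bounded-outcome
  rescaling. For rare outcomes the two can differ by an order of magnitude
  while sharing a sign; both are reported.
* **Absolute equity gap** $AEG$ = weighted coverage in the top 20% of $F$
  minus the bottom 20%, with quintiles cut at cumulative-weight fractions so
  ties never straddle a boundary.
* **Equity level** $1 - |CI_W|$, rounded to two decimals for report tables.
* **Confidence bounds.** The gap uses
  $AEG \pm 1.96\sqrt{s^2_{Q5}/n_{Q5} + s^2_{Q1}/n_{Q1}}$ with within-quintile
  variances and Kish effective sizes. For the index, the literal
  $CI \pm 1.96\sqrt{\operatorname{Var}(y)}$ form is available as
  `conf_mode = "as_printed"`, but its half-width does not shrink with sample
  size and is implausibly wide next to published survey intervals; the
  default `"estimator"` mode divides the variance by the effective sample
  size $(\sum w)^2 / \sum w_i^2$, which tracks the width of published
  coverage intervals. Choosing the scaled form as default (while keeping the
  literal one switchable) is a deliberate design decision.

### Decomposition

The index is attributed to model covariates in the
Wagstaff–van Doorslaer–Watanabe style adapted to the logistic link:
$\text{contribution}_k = (m_k \bar{x}_k / \mu) \, C_k$, with $m_k$ the
*average marginal effect* of column $k$ (each dummy switched $0 \to 1$ for
every child holding the rest; the average derivative
$\overline{p(1-p)}\,\beta_k$ for continuous age) and $C_k$ the concentration
index of the column against the same $F$ used for the outcome. Numerical
average marginal effects were chosen over an index-function linearization
because they are the standard device for binary-outcome decompositions and
are reproducible without further modelling assumptions. Shares are signed
percentages of $CI_W$; the residual absorbs what the covariates do not
explain, and shares plus residual sum to exactly 100 by construction.
Negative shares are meaningful (a factor that pulls against the overall
gradient) and are never clipped. When $|CI_W|$ is below $10^{-8}$ percentage
shares are suppressed (returned as `NA`) and absolute contributions reported
instead.

## Outcome definitions and the schedule

The default schedule is Uganda's routine childhood programme: BCG and OPV
birth dose at birth, DPT/OPV/PCV 1–3 at 6/10/14 weeks, MCV1 at 9 months. Due
ages are configuration, not hard-coded truth. Ages are handled in completed
months (`floor(due_days / 30.44)`) because that is how household surveys
store them.

* **ZERO**: no scheduled dose received. Published definitions vary between
  "received no vaccines" and "no vaccines by 12 months"; the default counts
  any unvaccinated child as zero-dose while flagging the under-12-month
  unvaccinated as *underage* (at risk of becoming zero-dose) — that flag is
  the fair covariate that lets the decomposition separate "too young" from
  genuinely missed children. A `zero_dose_rule = "strict"` switch restricts
  ZERO to children of 12 months and older.
* **FULL** (under 24 months): every dose due at the child's age received.
  A newborn whose only due doses are the birth doses is trivially fully
  immunized for age if those are received; this boundary case is deliberate
  and flagged here for sensitivity analyses.
* **COMPLETE** (24 months and older, boundary child included): the entire
  schedule received.
* Missing dose records count as *not received*, with a logged tally — the
  conservative convention for survey immunization data; the column-mapping
  reader can instead declare any recode for "don't know" codes.

## The synthetic generator

`simulate_population()` emulates the structure of a DHS-style child file:
categorical strata with declared sampling probabilities, ages uniform over
0–59 months, a latent standard-normal SES factor with a battery of ten
binary assets loading on it (log-odds loading 1.5, giving realistic asset
correlations around 0.3–0.5), survey weights (all 1 by default, lognormal on
request), and per-dose receipts drawn
$\text{Bernoulli}(\operatorname{logit}^{-1}(\text{planted effects}))$ *only
for doses already due*. Receipts are independent across doses given
covariates by default; a `monotone` flag imposes the near-monotone drop-out
pattern of real schedules (dose $k$ requires dose $k-1$) so both regimes of
the FULL/ZERO logic are testable. An optional missing-at-random rate stresses
the missing-dose handling; no informative-missingness model is provided
because published sources do not describe one.

What the generator does *not* emulate: cluster/stratified sampling designs
(weights are independent of covariates), card-versus-recall measurement
error, age heaping, or correlation between covariates (region and education
are drawn independently). Passing tests therefore demonstrate correctness of
the estimators under a clean logistic data-generating process, not
robustness to real survey pathologies.

Default problem sizes used in the validation suite: analytic-oracle
convergence checks use $n = 10^5$, decomposition-dominance checks
$n = 2\times10^4$–$5\times10^4$, null calibration 200 replicates of
$n = 2000$. These sizes put Monte-Carlo error well below the tested margins
while keeping the suite quick to run.

## Numerical choices and known limitations

* **Ties.** Fractional ranks give every member of a tie group the group's
  weighted midpoint rank; this keeps the weighted mean of ranks at exactly
  0.5 and makes the curve/covariance identity exact. Wealth quintiles are
  cut on scores rounded to 9 decimals so eigensolver floating noise cannot
  split a tie group.
* **PCA.** Assets are standardized to mean 0/variance 1 (correlation-matrix
  PCA) so rare and common assets are comparable; the score sign is oriented
  by a declared privileged asset (default: largest absolute loading
  positive). The PCA is weighted by the survey weights when they are
  supplied; published methodology does not state whether weighting was used,
  so the unweighted path is a matter of passing unit weights.
* **Structural zeros.** A dose that is not yet due cannot have been
  received, so the underage indicator quasi-separates every dose outcome.
  That is the fair covariate doing its job: the fitter lets its coefficient
  saturate (IRLS iteration cap raised to 100) and exempts it from the
  separation guard, while any *other* covariate driving fitted probabilities
  to 0/1 is reported as separation with the offending level named.
* **Finite-sample offset of the composite index.** Because the ranking model
  is fitted on the same data it ranks, the composite $CI_W$ has a small
  positive expectation even under a perfectly equal-access data-generating
  process (about $+0.036$ at $n = 2000$ with the default covariate set,
  shrinking with $n$ and growing with model size). The wealth-only index,
  whose ranking is exogenous to the outcome, is properly centred at zero.
  Comparisons of composite indices are therefore most meaningful across
  years/outcomes at similar sample sizes — the same caveat that applies to
  any direct-standardization index — and the null-calibration test checks
  the composite index against its own finite-sample null distribution.
* **Quintile coarsening.** The composite model carries SES as a quintile
  factor; when SES is the *only* driver of coverage, the composite index is
  systematically a few thousandths below the wealth-only index computed on
  the continuous score. This is expected discretization, not error.
* **Weights** enter as frequency-style weights in fitting and ranking;
  cluster-robust (survey-design) variance estimation is out of scope, so
  confidence bounds understate design effects in clustered surveys.

## A worked run

```{r example}
cfg <- sim_config(
  n_children = 4000,
  effects = list(DPT3 = list(intercept = 0,
                             residence = c(urban = log(4)),
                             maternal_education = c(higher = 0.5))))
pop <- simulate_population(cfg, seed = 2)
fit <- vaccine_equity("DPT3", pop)
fit
summary(fit)
plot(fit)
```

The planted pro-urban odds ratio of 4 surfaces as a positive concentration
index, a positive absolute equity gap, and a decomposition dominated by the
residence factor, with the underage/age block absorbing the fair variation
from children not yet due their third DPT dose.

For the full report bundle (per-outcome metrics for both rankings, stratum
coverage, long decomposition table, run log):

```{r pipeline, eval = FALSE}
run_pipeline(list(input = cfg, seed = 2), output_dir = "report")
```
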