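---
title: "Calibrating and predicting smoking prevalence under non-consent missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and predicting smoking prevalence under non-consent missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokemnar)
```

## The problem and the model

Birth registries that require maternal consent for smoking information carry
a sizeable group of births with *unknown smoking status*. If the decision to
withhold is related to true smoking — a smoker being more reluctant to
report — the data are missing-not-at-random (MNAR) and the prevalence
observed among consenting mothers is biased. Because the truth for
non-consenting mothers is unobservable, the question can only be approached
as a sensitivity analysis: posit an MNAR scenario, predict what the unknown
group would look like under it, and measure how much the combined estimate
moves.

`smokemnar` implements that programme in four stages.

**SGA-10 flagging.** Small-for-gestational-age (birth weight strictly below
the sex- and gestational-week-specific 10th percentile) is used as a
smoking-sensitive proxy for fetal growth inhibition. The reference is built
empirically: per-stratum 10th percentiles with linear interpolation between
order statistics (`stats::quantile` type 7), strata under `min_stratum_n`
(default 50 births) pooled toward the modal week 39, cutoffs
monotone-rearranged to be nondecreasing in gestational week and floored at
500 g. The default reference population is known-status non-smokers: smoking
shifts the weight distribution downward, so including smokers would
contaminate the "standard" the flag is measured against. A record at exactly
the cutoff is *not* SGA; records with unknown gestational age cannot be
flagged and are excluded from SGA prevalences (counted and reported).

**MNAR calibration.** For year $t$, with $p_{obs,t}$ the observed combined
(daily + occasional) smoking prevalence among known-status births and
$r_t = \mathrm{SGA}_{unknown,t} / \mathrm{SGA}_{known,t}$ the SGA-10
prevalence ratio between the two consent groups, the target prevalence
assumed for the unknown group is

$$p_{target,t} = \min(p_{obs,t} \cdot r_t,\; 0.999).$$

The clamp, rather than an error, keeps the downstream case weights defined
(they require $p_{target} < 1$). Ratios below 1 are propagated with a
warning: the MNAR hypothesis is directional, but the statistic is well
defined either way, and forcing $r_t \ge 1$ would hide sampling noise rather
than remove it.

**Prevalence-matched prediction.** A stratified simple random subsample
(default 30%) of the year's known-status births is drawn, preserving smoking
prevalence to within one record. Smokers receive the case weight

$$w = \frac{p_{target}(1 - p_{sub})}{p_{sub}(1 - p_{target})},$$

the unique per-class multiplicative weighting whose weighted prevalence
equals $p_{target}$ *exactly* (an identity, asserted to machine precision in
the tests). The subset is split 70/30 into training and hold-out, stratified
again. Two classifier backends are provided:

* `logistic` — weighted logistic regression on the one-hot features with a
  small ridge penalty ($\lambda = 10^{-3}$, intercept unpenalised), fitted by
  IRLS. The penalty matters: one-hot cells with no smokers make the
  unpenalised likelihood quasi-separate, collapsing many predicted risks onto
  numerical 0/1 ties at which no usable prevalence-matched cutoff exists.
  Deterministic, no tuning; the default and the backend used in the
  large-scale validation runs.
* `nnet` — a single-hidden-layer feed-forward network, hidden units
  $\{1,3,5\}$ and weight decay $\{0, 0.01, 0.1\}$ selected by repeated
  stratified 10-fold cross-validation with 5 repeats, minimising *weighted*
  log-loss (the weights are part of the estimand, so the selection metric
  must carry them).

Features are 53 one-hot indicators in fixed blocks: maternal age group (4),
parity group (3), marital status (2), education including an explicit
`missing` level (4), origin region (5), notification form (2), hospital (17),
birth-weight quartile (4), infant sex (2), gestational-age group including
`unknown` (10). Birth-weight quartile boundaries are computed once on the
year's known-status subset and frozen for hold-out and unknown-group
encoding, so no information flows backwards. (Registry descriptions of this
feature set quote slightly different dummy counts, e.g. 54, without
enumerating; the package records its own count in the `feature_spec`
object.)

The threshold $\tau$ is the largest cutoff at which the weighted fraction of
training scores $\ge \tau$ reaches $p_{target}$, ties broken toward the
larger cutoff. Hold-out accuracy is the unweighted agreement of the
thresholded classification with the recorded label; predicted prevalences
(hold-out and unknown group) are classified fractions with Wilson score
intervals — the Wilson interval is used because it behaves sensibly at the
small prevalences of the late cohorts, and is cross-checked against
`prop.test(correct = FALSE)` in the tests. Per-year seeds are
`base_seed + year` and are recorded in the output.

**Combination.** $p_{combined}$ is the count-weighted mean of $p_{obs}$ over
known births and the predicted prevalence over unknown births. Both a
relative change (percent of $p_{obs}$) and an absolute change (percentage
points) are reported, the relative change as the headline, because "a change
of x%" is ambiguous between the two; CSVs keep full precision and printed
tables round prevalences to one decimal of percent.

The missingness-regression module is methodologically separate: a log-link
GLM (Poisson family by default — the standard robust risk-ratio estimator
for a binary outcome; log-binomial as the alternative, started from the
Poisson solution because log-binomial IRLS is fragile) with a
mother-clustered sandwich variance, since mothers contribute several births.
CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$; at registry scale a
$t$-correction would be cosmetic. Education enters with an explicit
`missing` level: education missingness concentrates among non-Nordic
mothers, and dropping those rows would distort the origin risk ratios.

## What the synthetic registry emulates — and what it does not

The generator (`registry_config()` / `generate_registry()`) draws annual
cohorts (default 16, 1999–2014) with:

* smoking prevalence declining logit-linearly 26% → 7%, with the
  occasional-smoker share of all smokers drifting from 3/26 to 1/7; the
  yearly intercept is solved numerically so the marginal matches the trend;
* steep social gradients of smoking (education, origin region, marital
  status, age, parity). The gradients are deliberately strong: they are
  calibrated so per-year classifiers reach hold-out accuracies around
  0.90–0.95, emulating the near-separable regime that published registry
  analyses of this feature set report (accuracies up to 1.0). Real Norwegian
  data do show extreme smoking odds ratios across education strata, but the
  synthetic gradients should be read as an emulation device, not estimates;
* birth weight: normal with class means 3536/3519/3428 g
  (non-smoker/occasional/daily), residual SD 450 g, a 110 g-per-week
  gestational-age slope centred so class means are preserved, and a 120 g
  sex difference;
* unknown smoking status from a log-risk model — the same family the
  regression module fits, so injected risk ratios are directly recoverable —
  with electronic-form RR 0.58, origin-region RRs 1.09–1.26, hospital RRs
  0.40–2.40, cell probabilities clamped to (0, 0.95], the yearly intercept
  solved against an unknown-status trend shaped 8% (1999) → 19% (2007) →
  10% (2014), and `mnar_delta` as the log-risk increment for true smokers;
* mothers recurring across cohorts (≈1.6–1.7 births per mother), which is
  what gives the cluster-robust variance something to do; parity increments
  with each birth;
* 0.5% of records with unknown gestational age, and 0.2% non-viable records
  (weight < 500 g and/or gestation < 22 weeks) for `exclude_nonviable()` to
  remove.

`mnar_delta` defaults to $\log 1.1$: a mild MNAR scenario. Cotinine
validation studies of mothers who decline to report smoking suggest their
true prevalence is close to — sometimes below — that of reporters, so a
mild positive default is the defensible centre of the sensitivity range. It
is also the regime in which the SGA-ratio calibration can work at all (next
section).

Deliberately not emulated: under-reporting among consenting mothers (the
synthetic observed status equals the true status whenever it is not
unknown), smokeless-tobacco use, BMI, covariate effects on birth weight
other than smoking/gestation/sex, within-hospital form adoption patterns,
and consent-variable missingness as distinct from non-consent. Passing the
recovery tests therefore shows the *pipeline* is correct and near-unbiased
when its MNAR assumption matches the data-generating mechanism — it does not
certify the assumption in any real registry.

## A structural property of the SGA-ratio calibration

If smoking is the only channel linking SGA to consent, with $a$ the
non-smoker SGA risk and $a + \Delta$ the smoker SGA risk, then
$r = (a + \Delta q)/(a + \Delta p)$ for true unknown-group prevalence $q$
and observed prevalence $p$, and

$$p \cdot r = q \iff a(p - q) = 0.$$

So the scaled target *always* undershoots $q$ (for $q > p$) — at realistic
effect sizes ($\Delta/a \approx 0.4$ here) it recovers only ~10% of the
excess. Two consequences shape the package defaults. First, the prediction
stage, not the calibration, has to close the gap: the error of a
prevalence-matched classifier is approximately $(1 - \mathrm{TPR})$ times
the target's error, so high classifier discrimination makes the chain
nearly unbiased even with an attenuated target. Second, large observed SGA
ratios (such as 1.06–1.24 in real registries) cannot be produced by smoking
alone; they imply covariate composition differences between the consent
groups, and scaling by them transfers that composition effect onto smoking.
This is the central caveat of the method, and it is why the recovery
criterion is only attainable in the mild-MNAR, high-discrimination regime
the defaults encode.

## Numerical choices and edge cases

* Quantiles: type 7 everywhere (stated because conventions differ).
* Thresholds: with all scores identical, $\tau$ is that score, with a
  warning — prevalence is unmatchable. The achieved weighted fraction is
  always reported next to $\tau$; its deviation from $p_{target}$ is bounded
  by the largest tied weight share at the cutoff.
* `mnar_weights` errors on single-class subsets; `sga_ratio` errors on an
  empty consent group or a zero known-group SGA prevalence (advice: pool
  years), and warns on a zero numerator.
* Year rows that cannot be calibrated or predicted are kept with explicit
  skip notes rather than dropped.
* Degenerate outcomes (all known or all unknown) raise a convergence error
  in the regression module; fitted risks above 1 under the log link produce
  a warning naming the pathology.
* Determinism: every stochastic operation takes a seed and restores the
  caller's RNG state (`withr::with_seed`); two runs from the same
  configuration and seed produce byte-identical CSVs and manifests.

## Problem sizes used in validation

The packaged validation suite runs, on one CPU in a few minutes: parameter
recovery over 20 seeded replicates of the default 16-cohort × 10,000-births
registry (logistic backend); a MAR null at 100,000 births per cohort;
100 seeded replicates of a two-cohort 25,000-births registry for CI coverage
of the log-risk regression; and 30,000-birth cohorts for SGA
self-consistency. These sizes were chosen as the smallest at which the
binomial noise floors sit comfortably below the tolerances being asserted.

## Known limitations

* The SGA-ratio target is attenuated toward the observed prevalence by
  construction (see above); reported combined changes are conservative when
  smoking truly drives non-consent.
* Prediction CIs are Wilson intervals on a classified fraction: they carry
  classification sampling error only, not model or calibration uncertainty,
  and the report footer says so.
* The log-binomial backend can fail to converge on covariate-rich models;
  the Poisson log-risk family with robust variance is the default for that
  reason.
* The two-column (unadjusted/adjusted) regression table refits one model per
  term; with many hospitals this is the slowest part of the regression
  module.
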