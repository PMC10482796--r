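---
title: "Belief updating over replication outcomes: models, classification, and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief updating over replication outcomes: models, classification, and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replibelief)
```

## The setting

A researcher reads the results of four experiments (one direct replication
A′ and three conceptual replications B, C, D) that all test the same theory,
and states their belief that the theory is true on a 0–100% scale. The
vignette design behind this package presents eight such scenarios
(`scenario_designs()`), spanning k = 0 to 4 significant results; each
participant faces four of them — one from each of the pairs {1,8}, {2,3},
{4,5}, {6,7} — so everyone sees k = 1, 2, 3 plus either k = 0 or k = 4.

The package asks two questions of such data. First, what *should* the
belief be? Second, which *strategy* does each respondent's pattern of four
beliefs most resemble?

## The four strategy models

All four models map the number of significant results k to a predicted
belief; by design none of them uses the composition of results (direct vs
conceptual) or the respondent's role — a deliberate simplification that
keeps the model space identifiable from four responses.

* **Bayesian inference (BI)** — the normative model. Each experiment is
  significant with probability 1−β (the power) if the theory is true and α
  (the significance level) if it is false. The posterior follows from
  Bayes' rule; the binomial coefficients cancel, and the prior π is kept as
  a free parameter (default 0.5, in which case it drops out). With α = 0.05
  and 1−β = 0.5, the posterior at k = 0…4 is 0.071, 0.593, 0.965, 0.998,
  0.9999 — already 97% at k = 2.
* **Deterministic vote counting (DVC)** — belief 1, 0.5 or 0 as k/N is
  above, at, or below one half.
* **Proportional vote counting (PVC)** — belief k/N.
* **Averaging prior belief and significance (APBS)** — belief (π + k/N)/2.

With π = 0.5 the three heuristics all predict 0.5 at k = 2 (BI does not),
and the models separate cleanly at k ∈ {0, 1, 3, 4} — which is what makes
classification from four responses possible at all.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | per-experiment false-positive rate | 0.05 | the conventional level, stated in the vignettes |
| `power` | per-experiment power 1−β | 0.5 (study style 2); the respondent's self-reported value (style 1) | style 2's vignette disclosed 0.5; style 1 asked respondents to report the power they had in mind |
| `prior` | prior belief π | 0.5 | the vignettes instruct a 50/50 prior |
| `sigma` | random decision error (SD of the response noise) | 0.10 fixed, or estimated as q | 0.10 is an a-priori choice; q is the cohort mean of each respondent's minimum model RMSE |

Beliefs are handled internally as proportions in [0, 1]; the 0–100% slider
scale is divided by 100 at ingestion, which is what fixes the units of
`sigma` and the truncation bounds.

## The classifier

For a respondent with responses \(x_1,\dots,x_j\) (j ≤ 4 after removing
missing values), the likelihood under model \(H_i\) is a product of normal
densities centred at the model's predicted belief for each scenario's k,
with SD σ, truncated — i.e. renormalised, not censored — to [0, 1]. DVC
and PVC predict exactly 0 or 1 at the extremes; the same renormalisation
handles those boundary means (half the mass is cut away, then the density
is rescaled). Posterior model probabilities use a uniform prior of 0.25
per model:

\[
P(H_i \mid X) = \frac{P(X \mid H_i)}{\sum_{m=1}^{4} P(X \mid H_m)}.
\]

Likelihoods are accumulated in log space and normalised with log-sum-exp,
so posteriors remain defined when all four likelihoods underflow linearly.

**Screening.** Before classification a record is excluded if (i) three or
four of its four beliefs are missing, (ii) its beliefs, ordered by
ascending k, ever decrease ("irregular": every candidate model predicts a
weakly monotone pattern, so such records fit none of them), or (iii) study
style 1's BI model needs a self-reported power that is missing. With one
or two missing responses, likelihood and RMSE simply use the available j
responses.

**Benchmark gate.** Model fit is measured by RMSE between predictions and
responses. A respondent is only assigned to a candidate model if that
model's RMSE is *strictly* lower than the RMSE of a benchmark "model": the
horizontal line at the respondent's own mean belief (its RMSE is the
population SD of their responses). The gate applies to the
highest-posterior candidate only — the benchmark is a fit yardstick, not a
fifth model in the posterior.

**Labels.** The *weak* label is the highest-posterior model (required to
be at least 0.25, automatic under uniform priors; a tie within 1e−12 of
the maximum leaves the respondent unassigned — no tie-break rule is
invented, since any would bias the category counts). The *strong* label
additionally requires the posterior to exceed 0.75, i.e. posterior odds of
at least 3 against the other three models combined. We describe the 0.75
threshold in odds terms because that is the natural reading of the
posterior ratio p/(1−p); note that the likelihood-ratio of one model
against the equal-weighted composite of the other three would be 9 at the
same threshold, so "odds of 3" is a statement about posterior odds, not
about that composite likelihood ratio.

**Choosing σ.** Two settings mirror the original sensitivity design: the
a-priori σ = 0.10, and σ = q, where q is estimated on the screened sample
(after any k-subset restriction, before benchmark gating — the benchmark
is not one of the four models and plays no role in q). `classify_cohort()`
also supports the k = 0–3 and k = 1–4 subsamples, selected by whether a
respondent's scenario set contains scenario 1 or scenario 8.

## The synthetic-cohort generator

`simulate_cohort()` inverts the classifier's own response model: each
simulated strategy follower draws a scenario set from the pairing scheme,
then draws each belief from the truncated normal centred at their
strategy's prediction with SD `sigma_sim`. Study style 1 respondents also
draw a self-reported power from a normal with mean 0.67 and SD 0.20
truncated to (0.05, 1] — the two usable moments of the published summary
(the mode, 0.80, is not separately enforced). Irregular responders draw
four beliefs i.i.d. uniform on [0, 1]; with four distinct k values they
pass the monotonicity screen with probability 1/24. Missing responses are
blanked completely at random at the configured per-response rate. Both
the uniform-irregular and the missing-completely-at-random choices are
modelling assumptions: the source data characterise neither process.

By default responses keep full floating precision; `round_percent = TRUE`
rounds to whole percentage points to mimic the survey slider. The noise
family defaults to the truncated normal the classifier assumes (the
well-specified case, the only regime in which the classifier's posteriors
are directly interpretable); `noise_family = "uniform"` provides a
mis-specification probe of matched SD.

### What the simulations do and do not show

Recovery experiments (`run_recover()`) demonstrate that the pipeline is
*internally* consistent: when responses really are strategy predictions
plus truncated-normal noise, the classifier recovers the generating
strategy for ≥ 90% (empirically ≈ 99% at σ = 0.05) of the respondents that
survive screening, and recovery degrades as σ grows. They do not show
that real respondents use these four strategies, that real decision noise
is truncated-normal with a common σ, or that real irregular responding is
uniform — conclusions about real cohorts inherit all of those assumptions.

Two behaviours of the screen are worth knowing. First, recovery is
reported *conditionally on passing the monotonicity screen*: at σ = 0.05
the BI predictions at k = 3 and k = 4 differ by ~0.002, so roughly half of
genuine BI followers produce a non-monotone quadruple and are screened out
as irregular — indistinguishable, by construction, from true irregulars.
Second, the proportion of *strong* assignments falls steeply with σ, so
noisy cohorts show large unassigned fractions even when every respondent
follows a strategy.

## Numerical choices

* Truncated-normal density: `dnorm(x, mu, sigma)` divided by
  `pnorm(1, mu, sigma) − pnorm(0, mu, sigma)`, evaluated on the log scale
  inside likelihoods; sampling is by inverse-CDF, which keeps simulation
  deterministic given the seed.
* Posteriors: log-sum-exp normalisation; linear- and log-space
  computations agree to 1e−9 wherever the linear path does not underflow.
* q on a literally noise-free cohort is exactly 0; classification then
  floors σ at 1e−6 so the likelihood stays defined (exact followers are
  still recovered with posterior ≈ 1).
* Weak-label ties are declared at 1e−12; benchmark comparison is strict
  (`<`), so constant responders — whose benchmark RMSE is 0 — are always
  unassigned.
* σ self-consistency is assessed by the mean *log* posterior of the true
  model (a proper score, maximised by the generating σ); the raw mean
  posterior is not suitable — a too-small σ pushes correct posteriors
  toward 1 and can beat the true σ on average while being badly
  overconfident.

## Problem sizes

The shipped tests and recovery experiments use cohorts of 120–5,000
simulated respondents (400 for the headline recovery runs at σ ∈ {0.05,
0.10, 0.20}; 5,000 for the irregular-screen rate, whose combinatorial
expectation 23/24 needs a tight binomial check), with fixed seeds
throughout. These sizes give Monte-Carlo standard errors comfortably
below the margins being tested while keeping a full run in the order of a
minute or two.

## Known limitations

* Four responses cannot separate strategies whose predictions coincide on
  a respondent's particular k set; classification leans heavily on
  k ∈ {0, 1, 3, 4}. More experiments per scenario would separate the
  models further.
* The benchmark gate is conservative by construction: respondents with
  nearly flat response patterns are unassigned even if a model fits well
  in posterior terms.
* The multilevel regression analyses of belief on k, composition,
  preregistration status and p-hacking beliefs are out of scope here; the
  pipeline carries condition labels through unchanged so such models can
  be fit downstream with standard mixed-model tools.
* Real-survey ingestion is a thin, documented mapping onto the response
  CSV dialect (see the README), not a schema-aware reader for any
  particular survey platform export.
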