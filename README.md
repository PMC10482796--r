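# replibelief

How should a researcher's belief in a theory change after seeing the results
of four replication experiments — and how do researchers actually update?
`replibelief` implements both sides of that question as a tested, reusable
pipeline:

* the **normative Bayesian model**: the posterior probability that a theory
  is true given *k* significant results out of *N* experiments, each run at
  significance level α with power 1−β,

  P(H_A | k) = (1−β)^k β^(N−k) π / [ (1−β)^k β^(N−k) π + α^k (1−α)^(N−k) (1−π) ],

  with prior π (the binomial coefficients cancel; π = 0.5 recovers the
  familiar symmetric case);
* three **vote-counting/averaging heuristics**: deterministic vote counting
  (DVC: belief 1/0.5/0 as the proportion of significant results is
  above/at/below one half), proportional vote counting (PVC: belief = k/N),
  and averaging prior belief with significance (APBS: belief =
  (π + k/N)/2);
* a **per-participant Bayesian classifier** that assigns a response pattern
  to one of the four strategies: posterior model probabilities with uniform
  model priors, truncated-normal response likelihoods on [0, 1] with decision
  error σ (fixed at 0.10, or estimated as *q*, the cohort mean of each
  participant's minimum RMSE), an RMSE comparison against a
  participant-specific benchmark (the horizontal line at their own mean
  belief), weak (highest posterior) and strong (posterior > 0.75, posterior
  odds ≥ 3) labels, and screening of irregular (non-monotone), incomplete,
  and missing-power records;
* a **synthetic-cohort generator** for the eight-scenario vignette design
  (one scenario from each of the pairs {1,8}, {2,3}, {4,5}, {6,7}, so every
  participant faces k = 1, 2, 3 plus either k = 0 or k = 4) with known
  ground-truth strategies, truncated-normal decision noise, irregular
  responders and missingness — so every stage of the classifier can be
  validated by strategy-recovery simulation.

It is aimed at metascience researchers and statistics educators studying
statistical intuitions about replication, and at anyone who wants a
worked, testable reference implementation of vote-counting versus Bayesian
evidence synthesis over small study sets.

## Worked example

Two out of four experiments, each with 50% power, are significant. Starting
from a 50/50 prior:

```r
library(replibelief)
bayes_posterior_belief(2, 4, power = 0.5)
#> [1] 0.9651578
bayes_posterior_belief(0:4, 4, power = 0.5)
#> [1] 0.07126517 0.59315499 0.96515780 0.99810360 0.99990001
```

Belief in the theory is already 97% at k = 2 — vote-counting intuitions
("only half were significant, so it's a coin flip") badly underestimate the
evidence. The heuristics predict instead:

```r
pvc_predict(2, 4)   # 0.5
dvc_predict(2, 4)   # 0.5
apbs_predict(2, 4)  # 0.5
```

Simulate a cohort of known strategy users, classify it, and check recovery:

```r
cfg <- cohort_config(400, sigma_sim = 0.05, study_style = 2, seed = 105)
out <- run_recover(cfg, noise = noise_spec("fixed", 0.05))
#> [replibelief] simulate: 400 participants ...
#> [replibelief] classify: 400 in, 118 excluded (non_monotone=118), 282 analyzed; sigma = 0.05 (fixed)
#> [replibelief] recover: overall strong recovery 0.986, weak 0.996
out$confusion$strong
#>           assigned
#> true_model  BI DVC PVC APBS unassigned irregular excluded
#>   BI        43   0   0    0          0        60        0
#>   DVC        0  56   0    0          0        49        0
#>   PVC        0   0  97    0          1         0        0
#>   APBS      0   0   0    82          3         9        0
#>   irregular  0   0   0    0          0         0        0
```

98.6% of the participants that survive the monotonicity screen are strongly
assigned their true strategy. (Followers whose noisy responses happen to be
non-monotone — common for BI, whose predictions at k = 3 and k = 4 differ by
less than the noise — are screened out as "irregular" before classification,
exactly as real irregular responders are.)

Classify a response table from disk, with σ estimated as q, and summarise:

```r
cls <- run_classify("responses.csv", noise_spec("q"), out_dir = "out")
rep <- run_report(cls, "responses.csv", out_dir = "out")
rep$belief_by_k   # mean (SD) belief in percent for every k
```

A thin command-line wrapper with `simulate`, `classify`, `report` and
`recover` subcommands is installed at
`system.file("scripts", "replibelief-cli.R", package = "replibelief")`.

## Ingesting survey exports

The pipeline reads a long CSV with columns `participant_id`, `study_style`
(1 = power self-reported, 2 = power 0.5 stated in the vignette),
`condition`, `scenario_id` (1–8), `k`, `direct_significant`, `belief_pct`
(0–100, blank for missing) and `reported_power` (0–1, blank for missing).
To analyze an existing survey export, map each respondent's four scenario
responses onto those columns (one row per respondent × scenario) and pass
the file to `run_classify()`; `read_response_table()` validates rows and
reports offending line numbers.

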