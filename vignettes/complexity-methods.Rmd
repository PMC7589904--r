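---
title: "Methods: consensus scoring and complexity prediction for TURBT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus scoring and complexity prediction for TURBT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccs)
```

## The problem and the model

Transurethral resection of bladder tumours (TURBT) ranges from routine to
genuinely difficult. `bccs` implements a consensus pipeline that (i)
aggregates expert Likert judgements of candidate risk items, (ii) builds
random clinical vignettes from those items, (iii) models panel-judged
complexity with logistic regression on five domain scores, and (iv)
collapses the model into a bedside checklist, the Bladder Complexity
Checklist Sum (BCCS). A *complex* TURBT is one ending in incomplete
resection, surgery beyond one hour, or a Clavien–Dindo grade ≥ 3
complication.

The central model is ordinary maximum-likelihood logistic regression,

$$p(\text{complex}) = \frac{1}{1 + \exp\{-(\beta_0 + \textstyle\sum_d \beta_d s_d)\}},$$

where $s_d \in \{1,\dots,5\}$ is the Median Opinion (MO) of the item
selected in domain $d$ (history, access, number, size, location). The MOs
enter as numeric scores, not factor levels: the checklist construction
relies on contributions of the form $\beta_d \times s_d$, which only makes
sense for a linear-in-score model. That is the model's key assumption — a
one-point MO increment carries the same log-odds increase anywhere on the
scale.

## Delphi aggregation

Panel responses are summarized per item by the sample median (MO) and a
95% interval; *consensus* holds when the interval fits inside two
consecutive scores $[k, k+1]$.

The study design leaves the interval's construction open, so two readings
are implemented and neither is asserted as the original intent:

* `order_statistic` (default): the exact, distribution-free binomial
  interval for the population median, $(x_{(k)}, x_{(n+1-k)})$ with the
  largest $k$ such that $P\{\mathrm{Bin}(n, 1/2) \le k-1\} \le 0.025$. For
  $n = 10$ this is $(x_{(2)}, x_{(9)})$ at 97.9% coverage. For $n < 6$ no
  two-sided interval reaches 95% and the sample range is used.
* `percentile`: the empirical 2.5–97.5 percentiles of the responses
  (type-7 interpolation), the "coverage interval of the distribution"
  reading.

Even panels can produce half-integer medians; the package rounds them *up*
by default (toward higher complexity — the conservative direction for a
safety instrument), configurably down. Missing responses are an error:
the design assumes complete panels.

Scenario verdicts use the same interval machinery: a scenario is
`not_complex` when the upper bound is at most 2 ("unlikely"), `complex`
when the lower bound is at least 3 ("may occasionally"), and
`inconclusive` otherwise; inconclusive scenarios are dropped before
modelling.

## The synthetic panel: what it emulates, and what it does not

The expert study's raw responses were never published, so a generative
stand-in supplies statistically structured inputs.

**Item rounds.** Each item has a latent complexity in $[1, 5]$ (the
catalog MO); a panelist reports
$\mathrm{clamp}(\mathrm{round}(\text{latent} + \mathcal N(0, \sigma)), 1, 5)$.
The second round pulls every response toward the item's first-round median
by a factor $c$ before re-rounding — the panel was shown the score
distribution and asked to confirm or adjust, and attraction to the
displayed centre is the simplest behavioural reading of that feedback; no
behavioural data exist to fit anything richer. Defaults
$\sigma = 1.4$, $c = 0.7$ were chosen once so that a 10-member panel
reaches consensus on roughly half of 85 items in round one and nearly all
in round two, the pattern the study reports.

**Scenario ratings.** A scenario's latent probability is
$p = \mathrm{logit}^{-1}(\beta_0 + \sum_d \beta_d s_d + u)$ with the
published coefficients as the generative truth, where $u$ is a *shared*
scenario-level heterogeneity term, logistic with scale 1 on the logit
scale. This term is deliberate: a real panel reacts to the whole vignette
(item combinations, phrasing, clinical gestalt), not merely to the five
domain scores, so two scenarios with identical scores need not receive
identical verdicts. Without it, the consensus dichotomization — which
demands near-unanimity and discards the inconclusive middle — becomes a
deterministic threshold in the linear predictor, and any refit on the
classified scenarios is quasi-completely separated; no finite coefficient
estimates exist. Each panelist then perturbs $p$ by
$\mathcal N(0, 0.10)$ on the probability scale and reports the Likert band
of the result under cutpoints $(0.05, 0.2, 0.5, 0.8)$. The rating noise,
cutpoints and a case-mix weight of 6 on each domain's baseline item (most
real patients have unremarkable history and access) were fixed once
against the study's stated design conditions: about 87% of 150 scenarios
conclusive, with about 44% of those judged complex.

**What passing tests do not show.** The generator shares the analysis
model's functional form, so parameter-recovery results demonstrate the
correctness of the estimation code, not the adequacy of a linear-in-MO
logistic law for real surgical complexity. Panelist-specific bias or
leniency, item-specific ambiguity, and more than two rounds are all out of
scope.

**Dichotomization and recovery.** Coefficient recovery is validated by
drawing outcomes directly as Bernoulli($p$) with the heterogeneity term
disabled (`simulate_outcomes()`, `scenario_scale = 0`) — the exact
dichotomization of the generative truth, under which the refit is
unbiased; at 4000 scenarios every coefficient lands within 3 estimated
standard errors of its generating value in at least 19 of 20 seeds. The
panel path (ratings → consensus interval → dichotomize) does *not*
preserve the logistic law: aggregating ten near-agreeing ratings and
discarding the inconclusive middle steepens the induced link, so
coefficients refit through that path are systematically inflated. The
package therefore checks the panel path qualitatively (positive
coefficients, rank agreement with the truth), not by the 3-SE criterion.

## Scenario construction

One item per domain is drawn with probability proportional to its catalog
`frequency`, one scenario at a time, with rejection of draws that violate
a clinical-consistency rule (female + prostate items; male + prolapse) and
a cap of 1000 attempts — rules are sparse, so rejection is cheap and
exact. Sex follows the 2:1 male:female epidemiology of bladder cancer via
largest-remainder rounding, so 150 scenarios give exactly 100/50. Age
band and sex are carried for reporting realism but never scored (the
panel judged them to be of little influence), as are the two descriptor
domains (tumour structure, bladder anatomy); those descriptor items are
synthetic stand-ins, as the study's figure-level lists are not
machine-readable. The true per-domain sampling law of the original 150
vignettes is unstated; frequency-weighted sampling toward baseline items
is this package's choice and is flagged as such.

## Numerical choices

* **Mann–Whitney**: $U$ from rank sums with midranks; exact two-tailed p
  by full enumeration for combined $n \le 12$
  ($p = \min(1, 2\min(P(U \le u), P(U \ge u)))$); above that, the
  tie-corrected normal approximation with continuity correction, which
  stays within 0.05 of exact enumeration for all splits of eight distinct
  values. The screen retains domains with $p$ strictly $< 0.1$.
* **Logistic fit**: IRLS (`glm`, binomial) with tolerance $10^{-10}$ and
  at most 100 iterations; standard errors from the inverse observed
  information; no regularization, matching Wald-based reporting.
  Single-domain complete separation is detected up front and reported by
  name; a fit with any $|\hat\beta| > 50$ is flagged non-converged.
* **Checklist rounding**: weight = coefficient × MO rounded to the nearest
  multiple of a per-domain granularity, ties up. The granularity is
  per-domain (location 0.5, others 1.0) because the published table is
  internally inconsistent under any single rule — $1.44 \times 3$ prints
  as 4.5 while $1.10 \times 3$ prints as 3; this map reproduces every
  published weight from the published coefficients. The two dome-row
  companions ("anticipate obturator jerk", "diverticulum") are recorded
  under location; their domain is ambiguous in the published layout.
* **ROC/AUC**: trapezoid area over all distinct thresholds, equal to the
  tie-adjusted concordance probability; CI and the paired two-model test
  from the DeLong placement construction. Identical rankings give a zero
  variance of the difference; the comparison then returns $p = 1$ rather
  than 0/0.
* **Calibration**: slope = coefficient of $\mathrm{logit}(\hat p)$ in a
  logistic recalibration; CITL = intercept with the logit as fixed offset.
  Predictions exactly 0 or 1, or with zero logit variance, are errors.
  Deciles-of-risk bins are merged into a neighbour below 5 cases.
* **Predictive values**: PPV at threshold $t$ is
  $P(\text{complex} \mid \text{score} \ge t)$; an empty side is reported
  as missing with its counts, never as zero.
* **Randomness**: every simulation takes a single integer seed; pipeline
  stages derive named substreams from the master seed
  (`stage_seed(seed, stage)`), so any stage can be re-run in isolation.
  Helpers restore the caller's RNG state.

## Problem sizes

The shipped tests run the study-scale configuration (10 panelists, 85
items, 150 scenarios) for structural checks; parameter recovery uses 4000
scenarios × 20 seeds; calibration identities use 400–500 scenarios; the
type-I error of the paired AUC test uses 1000 replicates of $n = 400$; the
checklist/probability rank agreement is exhaustive over all $5^5$ score
combinations. The whole suite completes in well under a minute on one
core.

## Limitations

The package validates an analysis pipeline against its own generative
assumptions, not against clinical outcomes: the published headline numbers
that depend on the unpublished panel data (discrimination of the real
panel's verdicts, its univariate p-values, its consensus counts) are
design targets for *structure*, not values this package can or does
reproduce. The published model's covariance is shipped as a diagonal
approximation (only marginal standard errors were printed), so confidence
statements that need the full covariance should refit. BCCS thresholds for
action, and any mapping from BCCS to real predictive values, require
clinical data.
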