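---
title: "Modelling food-choice trials: scoring, preference estimation and sharing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling food-choice trials: scoring, preference estimation and sharing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(foodchoice)
library(dplyr)
```

## The experiment and its data

`foodchoice` analyses tray-based food-choice experiments with
free-ranging primates. In each trial a tray offers four food items —
two factory-made ("processed": bread, peanuts) and two plant-based
("unprocessed": brinjal, cauliflower) — and observers log every event
with a timestamp in seconds: a food is reached for (`ATTEMPT`), eaten
(`CHOICE`), picked up and put back (`REJECT`), defended aggressively
(`AGGRESSION`), or handed on to a group member (`SHARE`). The package
turns such event logs into ordinal descriptor scores, estimates
preference by conditional multinomial logit, and summarises sharing as
directed life-stage networks.

Because the animals, not individuals, visit the tray in groups, the food
item is the unit of analysis: every trial contributes one record per
food.

## Scoring model

Each trial yields five per-food descriptors:

* **FA** (first attempt) and **FC** (first choice) are order statistics:
  with four foods the first attempted (eaten) food scores 5, the next 4,
  and so on; a food never attempted (eaten) scores 1. With an extended
  vocabulary of k foods the top score generalises to k + 1.
* **RJ** counts rejection events between a food's first attempt and its
  consumption, capped at 8. The endpoints are fixed by the scoring
  protocol (0 = never rejected, 8 = rejected at the first attempt and
  never consumed); we read the intermediate values as a capped count,
  and apply the cap value to any rejected-but-never-eaten food. Whether
  a food rejected eight times can still be eaten later is not specified
  by the protocol; we allow it (the count simply saturates).
* **AG** is a saturating indicator of aggression over the food.
* **delay** is the latency FA→FC in seconds. The protocol anchors three
  values: 0 = no delay, 4 = the trial's maximum delay, 5 = approached
  but never eaten. We complete the scale by ranking the positive delays
  within the trial, anchoring the largest at 4 and counting down. The
  alternative — binning delays across the whole study — would make a
  trial's scores depend on other trials, which the within-trial ranking
  avoids. Unattempted foods score 0 with the latency undefined, since 5
  is explicitly tied to "approached".

Field logs have 1-second resolution, so ties happen; all scorers break
ties by log order (stable sorts), which makes scoring reproducible on
re-reads of the same file.

## Preference model

Preferences are estimated with an alternative-specific-constant (ASC)
conditional multinomial logit. Each trial is a choice among the four
always-available alternatives; the outcome is the first-attempted food
(model set 1) or the first-eaten food (model set 2). With utilities
$v_j = \alpha_j$ (one fixed at 0 for the reference alternative) the
choice probability is $P(y = j) = e^{v_j} / \sum_k e^{v_k}$.
Optionally the descriptor scores enter as alternative-varying covariates
($v_{ij} = \alpha_j + x_{ij}'\gamma$); the default is ASC-only because
the published preference tables report only per-alternative estimates.

Fitting is Newton–Raphson on the analytic gradient and Hessian from
$\beta = 0$ — i.e. from equal 0.25 alternative shares, matching the
equal-availability design — with step-halving if a step fails to
increase the likelihood, convergence at gradient max-norm
$< 10^{-8}$ (or likelihood change below the same tolerance), and at most
100 iterations. The covariance is the inverse observed information; z
and p are Wald statistics. If an alternative is never chosen its
constant diverges (complete separation); the fit warns, flags itself,
and downstream reports refuse to use it.

### LOCO reporting

Published tables of this design present four sub-models per set, each
"leaving one component out" as the reference alternative. We implement
the four sub-tables as re-parameterisations of **one** fitted model:
contrasts $u_j - u_r$ for every reference $r$, with delta-method
standard errors from the single fitted covariance. The printed tables
are exactly antisymmetric and transitive across blocks, which is the
signature of re-referencing one fit rather than fitting four separately
conditioned models — so this design reproduces their structure by
construction, and `loco_report()` guarantees both identities to machine
precision. `loco_from_contrasts()` applies the same re-referencing to a
published block of estimates directly, which is how the package checks
the internal consistency of printed tables without the raw data. Odds
ratios are the elementwise exponential of the contrasts; rankings sort
the fitted utilities, breaking exact ties alphabetically with a flag.
For bar-chart presentation `normalize_estimates()` min-max rescales each
block to [0, 1]; a constant block has no scale and maps to 0.5 with a
warning.

## Supporting statistics

These standard procedures are implemented from first principles, with
the corresponding base-R routines (`glm`, `cor.test`, `prcomp`,
`chisq.test`) serving as independent oracles in the test suite:

* **Correlations** between the five descriptors use the product-moment
  formula with two-sided p from the t transform on n − 2 degrees of
  freedom, optionally within each food. P-values are unadjusted, as is
  conventional in this literature's correlograms; a Holm option exists
  but is off by default.
* **Poisson GLM** regresses FC on FA, RJ, delay and AG with a log link,
  fitted by iteratively reweighted least squares from a zero start until
  the deviance changes by less than $10^{-10}$; deviance residuals are
  exposed for the usual residual check of fit.
* **PCA** eigendecomposes the descriptor correlation matrix by default:
  the descriptors live on heterogeneous ordinal scales (1–5, 0–8, 0–1),
  so the unstandardised covariance spectrum would be dominated by the
  widest scale. Covariance mode is retained because a near-unit loading
  of the 0–1 aggression score on the last component — as published
  analyses of this design show — is the signature of an unstandardised
  analysis; neither mode's field magnitudes are claimed. Components are
  ordered by eigenvalue and signs fixed so each component's dominant
  loading is positive.
* **Chi-square** tests (contingency and goodness-of-fit) use the Pearson
  statistic without continuity correction throughout — one consistent
  convention, and most tests of this design have df > 1 where the
  correction does not apply anyway.

## Sharing networks

Sharing events aggregate to one directed weighted graph per food over
the four life stages (adult, subadult, juvenile, infant); individual
identity is out of scope, matching the published presentation. Each
sharing incident is one link — repeated shares of a food within a trial
count separately — and self-loops (adult→adult) are real events and are
counted. Weighted in/out-degrees therefore both sum to the food's event
count, a conservation law the tests enforce. The shared fraction of the
item is carried through I/O but enters no statistic. The overall
sharing rate divides distinct shared (trial, food) cases by successful
(eaten) cases.

## The synthetic trial generator

No generative model is published for this design, so the package
defines one whose structure makes the estimator correctly specified —
parameter recovery is then a meaningful end-to-end test:

* **Attempt order** ranks per-food attempt utilities plus independent
  standard Gumbel noise, so first-attempt probabilities are exactly
  multinomial logit (the Gumbel-max construction).
* **Session truncation**: after each rank the session continues with
  probability `p_continue` (default 0.95 per rank), so late foods may
  stay unattempted (FA = 1) or attempted-but-uneaten (delay score 5).
* **Eating order** among attempted foods follows the choice utilities
  the same way (a Plackett–Luce sequence), truncated identically.
* **Rejections** per attempted food are geometric with success parameter
  `1 − p_reject`; a food that is attempted but never eaten ends with at
  least one rejection — abandonment *is* a final rejection — which is
  what links high rejection to non-choice in the scored data.
* **Delays** are exponential with mean `delay_scale` (default 30 s),
  rounded to whole seconds as in the field logs; a choice timestamp is
  clamped up to the previous choice when an independently drawn delay
  would contradict the drawn eating order, so FC frequencies keep the
  exact logit form at the cost of mild upward distortion of late
  delays.
* **Sharing** happens only for eaten foods, with probability
  proportional to `sharing_weights` anchored at an overall rate
  `p_share` (default 0.18 of eaten cases, the published sharing rate).
  The default weights are a steep inverse of the choice utilities,
  `exp(-4u)`, chosen so the least-preferred foods dominate sharing the
  way the field data report (roughly half of shares involving the
  least-preferred item); initiator and recipient stages draw from
  `stage_mix` (adult-heavy by default, as wild groups are).

Default utilities are the published bread-referenced contrasts
(attempt: brinjal 0.075, cauliflower −0.080, peanuts −0.293; choice:
brinjal −0.045, cauliflower −0.309, peanuts −0.374) and `n_trials = 74`,
so a default dataset emulates the study's conditions. One seeded
stream drives everything: the same `sim_config()` reproduces the same
event log byte for byte.

What the generator does **not** emulate: individual identity and social
rank, zone effects (zones are opaque labels drawn uniformly), satiation
across a session, human interference, and any dependence of rejection
counts on handling time. Passing tests on synthetic data therefore
validate the *machinery* — scoring rules, likelihood, re-referencing,
network bookkeeping — not field-data magnitudes.

```{r example}
cfg <- sim_config(n_trials = 74, seed = 1)
scores <- score_trials(simulate_trials(cfg))
fit <- fit_mlogit(build_choice_data(scores, "attempt"))
tidy(fit)
rank_preferences(fit)$food
```

## Problem sizes and numerical choices

The test suite checks distributional properties at the sizes where the
relevant standard errors are decisive: 10,000 trials for first-attempt
frequencies (binomial standard error ≈ 0.004 against tolerances of
0.02) and for the scoring-invariant sweep; 100 replicates of 500 trials
for ranking and utility recovery; 20 runs of 800 trials for the
modal-shared-food property. The Newton–Raphson fit is cross-checked
against a dense likelihood grid (step 0.01 over contrasts in [−3, 3])
on small three-alternative problems, and the closed form
$\hat\alpha_j = \log(n_j / n_{\mathrm{ref}})$ of the ASC-only model on
random count configurations.

One caveat deserves honesty: with 500 trials and attempt utilities
(0.4, 0.2, 0.0, −0.3) the implied first-attempt shares are
(0.335, 0.274, 0.225, 0.166), and the probability that a multinomial
sample of 500 orders all four counts correctly is only ≈ 0.89 — no
estimator monotone in the counts can do better. Full-ranking recovery
in ~89 of 100 replicates is therefore the *correct* behaviour of a
correct implementation at this sample size; the recovered contrasts are
essentially unbiased (mean absolute bias well under 0.01).

## Known limitations

* Covariate sub-models are provided but not claimed to match any
  published covariate estimates: which covariates entered which
  published model is not specified.
* Published field magnitudes (the contingency χ² across sites, per-food
  correlations, GLM and PCA values) depend on the deposited raw data
  and are out of scope; only their procedures and internal-consistency
  relations are validated here.
* The ambiguous denominator of "switching" percentages (per trial vs
  per attempted food) is left to the user: both `build_choice_data()`
  sets expose the ingredients.
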