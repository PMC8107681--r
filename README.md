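# foodchoice

Analysis of tray-based food-choice experiments with free-ranging
primates. Urban-dwelling folivores such as gray langurs are routinely
provisioned with factory-made food; choice trials that offer processed
(bread, peanuts) and unprocessed (brinjal, cauliflower) items on a tray
ask which foods the animals actually prefer when scarcity and human
interference are removed. `foodchoice` is for behavioural ecologists
running such experiments: it takes timestamped trial event logs from the
field through scoring, preference estimation, supporting statistics and
food-sharing network analysis, and ships a synthetic trial generator
with known ground truth so the whole pipeline can be validated by
parameter recovery.

## What it computes

**Scoring.** Each trial's event log (`ATTEMPT`, `CHOICE`, `REJECT`,
`AGGRESSION`, `SHARE` events with times in seconds) becomes five ordinal
descriptors per food: first attempt FA and first choice FC (5 = first,
1 = never), rejection count RJ (0–8, capped), aggression indicator AG,
and a delay score (0 = none, 4 = trial maximum, 5 = approached but never
eaten).

**Preference model.** An alternative-specific-constant conditional
multinomial logit: the probability that food *j* is attempted (or eaten)
first is

P(y = j) = exp(α_j) / Σ_k exp(α_k),

with one α fixed at 0. Maximum likelihood is by Newton–Raphson on the
analytic gradient and Hessian, from equal shares, with Wald inference.
`loco_report()` re-references the single fit into the standard
leave-one-component-out (LOCO) sub-tables — utility contrasts
u_j − u_r for every reference food r, delta-method standard errors, and
odds ratios exp(u_j − u_r) — which are exactly antisymmetric and
transitive across blocks. `rank_preferences()` orders the foods by
fitted utility.

**Supporting statistics.** Descriptor correlation matrices (overall and
per food), a log-link Poisson regression of FC on FA, RJ, delay and AG
fitted by IRLS, PCA of the five descriptors (correlation or covariance
mode), and Pearson chi-square tests (contingency and goodness-of-fit).

**Sharing networks.** Directed weighted graphs per food over the four
life stages (adult, subadult, juvenile, infant), with in/out-degree
summaries, sharing composition and the overall sharing rate.

## Worked example

```r
library(foodchoice)

cfg    <- sim_config(n_trials = 74, seed = 1)   # study-scale conditions
events <- simulate_trials(cfg)                  # timestamped event log
scores <- score_trials(events)                  # 296 rows: 4 foods x 74 trials
fit    <- fit_mlogit(build_choice_data(scores, "attempt"))
fit
#> Conditional multinomial logit (attempt set), reference: bread
#> n = 74 trials ( 0 excluded ); logLik = -100.398
#>          term estimate std.error statistic p.value
#> 1     brinjal   0.3023    0.3198    0.9451  0.3446
#> 2 cauliflower   0.2578    0.3229    0.7984  0.4246
#> 3     peanuts  -0.3483    0.3770   -0.9238  0.3556
```

The estimates are utility contrasts against bread: positive means
attempted before bread more often than chance. Re-referencing gives the
published-style sub-tables — here the peanut-referenced block, whose
odds ratios say how many times more likely each food is to be attempted
first than peanuts:

```r
loco <- loco_report(fit)
subset(loco, reference == "peanuts")
#>   stage   reference alternative estimate std.error statistic p.value odds_ratio
#> 1 attempt peanuts   bread          0.348     0.377     0.924  0.356        1.42
#> 2 attempt peanuts   brinjal        0.651     0.356     1.83   0.0677       1.92
#> 3 attempt peanuts   cauliflower    0.606     0.359     1.69   0.0912       1.83

rank_preferences(fit)$food
#> [1] "brinjal"     "cauliflower" "bread"       "peanuts"

comp <- sharing_composition(sharing_events(events),
                            eaten_cases = sum(scores$fc > 1))
sprintf("sharing rate: %.1f%%", 100 * comp$sharing_rate)
#> [1] "sharing rate: 19.7%"
```

At 74 trials the standard errors are wide (≈ 0.32–0.38), so a single
simulated study recovers the generating order only roughly — which is
exactly the sampling behaviour the recovery tests quantify.

A full run (`simulate → score → fit → loco → stats → network`, with
per-stage CSV/JSON outputs and a reproducibility manifest) is one call:

```r
run_pipeline(run_config(out_dir = "out", seed = 7))
```

or, from a shell, `Rscript inst/cli/foodchoice.R run --seed 7 --out out`.

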