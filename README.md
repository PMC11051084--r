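# lapsepipe

Interruption detection and period inference for online-learning event
logs.

## The problem

Learners using web-based study platforms get interrupted — by phones,
flatmates, naps, camping trips — and a platform only sees the timing
residue of those events: a question attempt that took 20 minutes instead
of 30 seconds, or a session that timed out half way through a module.
`lapsepipe` turns a tabular interaction log (one row per timed question
attempt or feedback review) into per-record interruption flags,
per-period interruption rates, and effect-size comparisons between
calendar periods. It is aimed at learning-analytics researchers and at
instructors who want to know how often, and when, their students'
digital study time is broken.

## Methods at the core

Duration statistics are always computed per item and per *stratum* —
initial attempt, subsequent attempt, initial feedback review, subsequent
feedback review — because repeat encounters are systematically faster
than first ones. Three within-session classifiers and one
between-session detector are provided:

1. **Fixed threshold** — an interaction is an interruption iff its
   duration exceeds `mean + k·SD` of its (item, stratum) group
   (default k = 2).
2. **Speed-adjusted threshold** — each learner gets a *speed factor*
   per stratum, `s = Σ(own durations) / Σ(item mean durations)` over the
   items they encountered; the record is flagged iff
   `duration > s · T`. A learner half as fast as average has s = 0.5 and
   a proportionally lower bar.
3. **Modified Z-score** — with `x = ln(duration / s)`, flag iff
   `M = 0.6745 · (x − med(x)) / MAD > 3.5`, where
   `MAD = med(|xᵢ − med(x)|)` per (item, stratum). Robust to the very
   outliers being detected; one-sided (fast outliers are never flagged).
4. **Session reconstruction** — within a learner × module attempt, an
   inactivity gap `start[i+1] − (start[i] + duration[i]) ≥ 30` minutes
   ends a digital session; a module completed in *s* sessions had
   *s − 1* *long interruptions*.

The inference layer aggregates flags by UTC calendar month and by named
periods (defaults: pre-COVID Jan 2019–Feb 2020, peak COVID Apr–May 2020,
post-peak Jun 2020–Dec 2022, March 2020 excluded), runs the test of
equal proportions (Pearson χ², df = k − 1), and compares period pairs
with Cohen's h

```
h = 2·arcsin(√p₁) − 2·arcsin(√p₂)
```

against a pre-declared smallest effect size of interest (SESOI; defaults
0.5 for the pre-vs-peak contrast, 0.3 otherwise). Within-session and
long-interruption rates are disjoint event classes over the same
denominator, so their sum is the overall interruption rate.

Because real platform logs are proprietary, the package includes a
synthetic event-log generator (`simulate_eventlog()`) with ground-truth
interruption labels: lognormal per-stratum base durations (initial
attempts median ≈ 28 s, subsequent ≈ 12 s), multiplicative learner speed
heterogeneity, injected additive pauses, and injected ≥ 30 min breaks.

## Worked example

```r
library(lapsepipe)

log <- simulate_eventlog(eventlog_config(n_learners = 30, seed = 7))
rec <- log$records

st  <- stratum_stats(rec)                 # per (item, stratum) mean/SD/median
th  <- duration_thresholds(st, k = 2)     # T = mean + 2·SD, min n = 5
fx  <- compute_speed_factors(rec, st)     # per (learner, stratum) pace ratio
cls <- classify_adjusted(rec, th, fx)     # speed-adjusted classifier
cls
#> <lapse_classification:speed_adjusted> 148/1578 flagged (rate 0.09379), 33 rejected

parts <- partition_sessions(rec, timeout_minutes = 30)
lir <- long_interruption_rate(parts, rec)
combine_rates(cls$rate, lir$rate)
#> [1] 0.09937  (within-session 0.09379 + long 0.00559)

period_report(rec, cls)
#> <period_report:speed_adjusted>
#>        period interruptions interactions       rate
#> 1:  pre_covid            51          455 0.11208791
#> 2: peak_covid             6           76 0.07894737
#> 3:  post_peak            88         1024 0.08593750
#> equal proportions: chi2(2) = 2.741, p = 0.254
#>            p1         p2           h sesoi     verdict
#> 1:  pre_covid peak_covid  0.11315471   0.5 below_sesoi
#> 2:  pre_covid  post_peak  0.08773411   0.3 below_sesoi
#> 3: peak_covid  post_peak -0.02542060   0.3 below_sesoi
#> unweighted mean monthly rate: 0.09736
```

Reading the output: 148 of 1,578 classifiable interactions exceeded
their learner-adjusted item thresholds (33 records sat in item groups
too small for a usable threshold and were rejected, not silently
dropped); the long-interruption rate adds 0.56% for a combined 9.9%.
The per-period rates differ but every pairwise Cohen's h is far below
its SESOI: no practically meaningful period effect. A desk-scale cohort
like this over-flags relative to a production deployment — with ~50
records per item group the mean + 2 SD bar is noisy; rates stabilise
near 2–3% as group sizes grow into the thousands.

Period-level counts from a published billion-interaction deployment ship
with the package for the inference layer:

```r
t1 <- published_period_counts(study = 1, comparison = "hypothesis")
equal_proportions_test(t1$interruptions, t1$interactions)$chi2
#> [1] 107.1587
cohens_h(6107869/301995418, 830424/41255775)
#> [1] 0.0006895  (pre-COVID vs peak COVID: negligible)
```

## Command line

An installed `exec/lapsepipe` script exposes the pipeline:

```sh
lapsepipe simulate --out sim/ --seed 5 --learners 50
lapsepipe study2 --log sim/events.csv --out s2/   # speed-adjusted flags
lapsepipe study5 --log sim/events.csv --out s5/ --timeout-min 30
lapsepipe compare --flags s2/flags.csv --out report/
```

## Package layout

- `R/eventlog.R` — CSV I/O, validation, stratum derivation, module grouping
- `R/simulate.R` — ground-truth-labeled synthetic cohort generator
- `R/threshold.R`, `R/speed_factor.R`, `R/robust.R` — the three classifiers
- `R/sessions.R` — session reconstruction, long-interruption rate
- `R/inference.R` — periods, monthly rates, χ², Cohen's h, SESOI
- `vignettes/interruption-detection.Rmd` — models, assumptions, design
  choices, and what the synthetic tests do and do not establish
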