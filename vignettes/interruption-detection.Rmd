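---
title: "Detecting interruptions in online-learning event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interruptions in online-learning event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapsepipe)
```

## The data model and its assumptions

An event log has one row per timed interaction: a learner's attempt to
answer an item, or their review of that item's corrective feedback. The
platform logs the duration directly; `lapsepipe` treats it as opaque (no
clock reconstruction from consecutive timestamps) and requires it to be
positive. Timestamps are interpreted in UTC throughout — the source data
carry no timezone, and one fixed convention keeps calendar-month
assignment reproducible. Encounter order within a learner × item × kind
group is derived by sorting on start time, with ties broken by stable
input order, again for determinism.

The four strata — initial attempt, subsequent attempt, initial feedback,
subsequent feedback — exist because repeat encounters are much faster
than first encounters (medians of roughly 12 s vs 28 s for attempts in
the deployment the packaged period counts come from). Pooling them would
make every subsequent encounter look fast and every initial one slow.

Every ingestion and classification step keeps a rejects channel: rows
that fail validation, records in item groups too small to classify, and
attempts with overlapping records are counted and surfaced, never
silently dropped.

## The classifiers

**Fixed threshold.** `duration > mean + k·SD` per (item, stratum), k = 2
by default. The inequality is strict, so a degenerate group (all
durations equal, SD = 0) flags nothing. Statistics use the sample (n−1)
SD and are computed over *all* records of a group — including the
outliers being hunted, which inflate both mean and SD. That circularity
is a known weakness of the method, and it is why the robust classifier
exists.

**Speed adjustment.** The speed factor for a learner and stratum is the
ratio of their total duration to the total of the cohort item means over
the same interactions. The denominator sums per-interaction means (an
item met twice contributes its mean twice), mirroring the numerator so
that an exactly-average learner has s = 1 identically. Learners with
fewer than `min_interactions = 3` records in a stratum fall back to
s = 1: a factor estimated from one interaction would make that very
record unflaggable in expectation. Factors are estimated in-sample from
the records being classified; that is faithful to the method as used in
practice, and its consequences are discussed under *Limitations*.

**Modified Z-score.** `x = ln(duration / s)` tames the strong right skew
so a location/scale rule is sensible; the score
`M = 0.6745 (x − med x) / MAD` uses the unscaled MAD (the 0.6745
coefficient plays the role the usual 1.4826 consistency constant would).
The cutoff is 3.5 and the rule is one-sided: anomalously *fast*
interactions indicate a different behaviour (skimming, gaming) and are
out of scope. A group with MAD = 0 — more than half its mass at the
median — flags nothing and is reported as degenerate; refusing to divide
by zero is conservative and visible, rather than substituting a
mean-based deviation.

**Session reconstruction.** The inactivity gap before interaction *i+1*
is `start[i+1] − (start[i] + duration[i])`. A gap of at least the
platform timeout (default 30 minutes) ends the session; the boundary
case counts as a timeout because the platform logs the learner out *at*
the timeout. Only completed modules contribute long interruptions — an
incomplete attempt's trailing gap may simply be "has not come back yet"
— and a module completed in *s* sessions had *s − 1* long interruptions.
Whether the logged duration of the final interaction before a timeout
includes idle time is unknowable from the data; the reconstruction
assumes it does not.

## Inference across calendar periods

Default periods: pre-COVID January 2019–February 2020, peak COVID
April–May 2020, post-peak June 2020–December 2022, with March 2020
excluded as a transition month; `seasonal_config()` builds April–May
windows per year to control for seasonality. The test of equal
proportions is the Pearson χ² on the k × 2 table (as `prop.test()`
computes it, continuity correction only on request and only for k = 2).
Because the deployment-scale denominators make *any* difference
statistically significant, the package leans on Cohen's
`h = 2 asin √p₁ − 2 asin √p₂` judged against a pre-declared SESOI
(defaults: 0.5 for pre-vs-peak, 0.3 elsewhere; the boundary counts as
reaching the SESOI). p-values are reported but never drive a verdict.
Monthly series report both the pooled rate and the unweighted mean of
monthly rates; months with zero classified interactions are omitted from
the unweighted mean rather than imputed.

Within-session flags and long interruptions are disjoint event classes
over the same interaction denominator, so `combine_rates()` is a sum —
e.g. the published 2.855% (speed-adjusted) + 0.351% (long) = 3.206%.

## The synthetic world

`eventlog_config()` states one world and the defaults are fixed, not
tuning knobs:

| parameter | default | why |
|---|---|---|
| base durations | lognormal; initial attempts meanlog = ln 28, sdlog = 1.156; subsequent meanlog = ln 12, sdlog = 1.046 | matches the published medians (28 s, 12 s) and means (54.6 s, 20.7 s) of the deployment's example item |
| feedback strata | medians 20 s / 10 s, sdlog 1.0 | no published anchors; round values between the attempt anchors |
| speed multipliers | lognormal, median 1, sdlog 0.35 | median-1 keeps the cohort calibrated; spread wide enough that speed adjustment matters |
| interruption probability π | 0.02 | the deployment-scale interruption rate (~2%) |
| pause distribution | lognormal, median 600 s, sdlog 0.75 | long-tailed, mostly above desk-scale thresholds and below the 30 min timeout; no canonical family exists, so the sampler is a config function |
| long-break probability | 0.175 per module attempt | ≈ long-interruption rate (0.351%) × interactions per module (~50) |
| organic gaps | Exp(mean 15 s), capped below the timeout | clicking cadence; the cap guarantees injected breaks are the only session boundaries |
| timeout | 30 min | the platform constant |

Durations are integer seconds so timestamps are exact and reconstructed
gaps equal injected gaps — the session-truth recovery test is exact, not
approximate. One master seed drives per-learner substreams, so the same
seed reproduces the log record for record.

What the generator does *not* emulate: answer correctness, mastery
scheduling, item content, weekday/semester rhythms, or any dependence of
interruption probability on time of day. A green recovery test
establishes that the classifiers find what the generator injected under
the generator's assumptions — not that real interruptions follow those
assumptions.

## The π-recovery world

The acceptance suite requires that injected interruption rates
π ∈ {0.01, 0.05, 0.1} be recovered within 3 binomial standard errors by
the fixed and speed-adjusted classifiers when pauses lie far above all
thresholds. That premise pins the world down more tightly than is
obvious, and the constraints are worth recording because they are
properties of the *method*, not of this implementation:

1. **Every item group must be contaminated.** A group that happens to
   receive no injected pause keeps a clean mean + 2 SD threshold, and
   such a threshold organically flags ~2% of any continuous unimodal
   tail. The expected number of clean groups, items · exp(−π · group
   size), must be ≈ 0 — at π = 0.01 that means ~1000 learners per item.
2. **In-sample speed factors self-mask.** A learner with k pauses among
   n stratum interactions has a pause-dominated factor ≈ k/(nπ), and
   their own pauses escape detection once
   k > nπ / (π + 2√(π(1−π))). A 3σ binomial excess of per-learner
   pauses must stay below that bound, giving n of roughly 78, 152 and
   240 interactions per learner-stratum at π = 0.01, 0.05, 0.1 (padded
   in practice for group-level threshold spread).
3. **Clean learners' factors are deflated** to about
   base/(base + π·pause), so the organic duration tail must clear the
   deflated adjusted thresholds; the recovery world uses a milder base
   spread (sdlog 0.5) than the realistic default.

Under the realistic default world these conditions fail and the
criterion is not attainable — which is precisely the published
motivation for the robust classifier and for treating session timeouts
as the only unambiguous interruptions.

## Numerical choices and degenerate inputs

- Thresholds and scores use strict `>`; boundary records are normal.
- Sample (n−1) SD; groups below `min_n = 5` records are unclassifiable
  and rejected (an SD from three observations is noise).
- MAD of an even count is the midpoint of the central order statistics.
- SD = 0 and MAD = 0 groups flag nothing, by the strict inequality and
  the refuse-to-divide rule respectively.
- Scale invariance holds exactly: multiplying every duration by c > 0
  leaves speed factors, speed-adjusted flags and modified-Z flags
  unchanged (thresholds scale; log-scores shift and cancel).
- A pooled proportion of 0 or 1 makes the χ² statistic 0 with a warning
  rather than an error.
- Thresholds are computed on the full data set passed in, not per
  period; recomputing them per period would let content drift mask real
  rate changes. Restricting to a sub-cohort (`restrict_cohort()`)
  deliberately requires recomputing stats and factors on the subset.

## Limitations

- All three duration classifiers infer disengagement from time alone; a
  learner reading slowly and one answering email are indistinguishable.
- The in-sample speed factor absorbs a learner's own interruptions into
  their estimated pace (see above); alternative factor definitions
  (median-based, ratio-of-means per item) are extension points, not
  implemented.
- Long gaps cannot be decomposed into multiple shorter disruptions.
- The packaged period counts support the inference layer only; the
  deployment-wide per-record rates (e.g. 2.017% for the fixed
  classifier) require the proprietary raw log and are out of reach of
  desk-scale verification.
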