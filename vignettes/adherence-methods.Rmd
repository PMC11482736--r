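---
title: "Scoring adherence to staged concussion protocols from accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring adherence to staged concussion protocols from accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Staged Return-to-Activity (RTA) protocols manage concussion recovery in
children and youth by restricting physical activity early and
reintroducing it gradually across six stages; a parallel five-stage
Return-to-School (RTS) protocol governs cognitive load.  Whether young
patients actually follow these protocols is usually judged from
self-report, which is known to be optimistic.  A waist-worn
accelerometer gives an objective record of movement, so adherence can
instead be scored from activity counts against the quantitative rules
the early protocol stages state.  `actiadhere` implements that scoring
chain end to end, together with the statistics used to ask the two
follow-up questions: do objective and self-reported adherence agree,
and do self-reported adherers recover faster?

## From raw epochs to valid days

Activity counts arrive as uniformly spaced epochs (30 s by default; 1,
5, 10, 15 and 60 s are accepted and re-aggregated by summation, since
counts are additive over time).  Processing per participant:

1. **Non-wear removal.**  The study this design follows relied on
   participant log diaries plus visual inspection by trained personnel.
   Visual inspection is not reproducible in software, so the package
   substitutes a standard zero-run rule: any run of consecutive
   zero-count epochs lasting at least `nonwear.zero_run_min` minutes
   (default 60) is flagged as non-wear and unioned with the logged
   intervals.  Both sources are treated identically; overlapping
   intervals remove an epoch once.
2. **Intensity classification.**  Each worn epoch is classed
   sedentary / light / moderate / vigorous by cut points on counts per
   epoch.  Defaults are the child-calibrated cut points expressed per
   minute of vertical-axis counts -- sedentary ≤ 100, light ≤ 2295,
   moderate ≤ 4011 counts/min, vigorous above -- scaled linearly to the
   epoch length with a floor, giving 50 / 1147 / 2005 per 30-s epoch.
   Upper bounds are inclusive.  The cut points are configuration, not
   constants, because count-scale calibrations differ across devices
   and age groups.
3. **Daily summaries.**  Days split at calendar midnight on the local
   study clock (a single-site design; no timezone arithmetic is
   performed).  A day is *valid* when wear time lies in the inclusive
   range 360--1140 minutes (6--19 h); "at least" and "no more than"
   both read inclusive.  Only valid days enter adherence scoring.

## The stage rules

Objective rules exist for RTA stages 1--3 only; later stages have no
quantifiable activity amounts, and requesting them raises an error
rather than guessing.  Writing `wear` for the day's worn minutes, `LPA`
for light minutes and `MVPA` for moderate-plus-vigorous minutes:

* **Stage 1** -- unlimited LPA; `MVPA ≤ 0.025 × wear` (the cap is a
  fraction of *worn* minutes, which is what "of wear time" means, not
  of the 24-h day); and no run of ≥ 5 min at any non-sedentary
  intensity.  A sedentary "bout" cannot violate a rest recommendation,
  so *any intensity* is interpreted as any non-sedentary class.
* **Stage 2** -- activity observed at stage 1 plus 30 extra minutes of
  LPA; no MVPA bout of ≥ 5 min.  "Baseline activity observed" is
  undefined in prose, and is operationalised as the mean daily class
  minutes over that participant's valid stage-1 days.  The stage-2 MVPA
  ceiling is that baseline MVPA (`stage2.mvpa_cap_mode = "baseline"`):
  the only reading under which stage 2 is stricter than stage 3, which
  explicitly grants extra MVPA.
* **Stage 3** -- stage-2 baseline plus 60 extra MVPA minutes, with at
  most two MVPA bouts of ≥ 5 min, each at most 15 min.  The bouts are
  counted *within* the extra 60 minutes, not on top of them; the text
  does not resolve this, and the inclusive reading is the conservative
  one.

A *bout* is a maximal run of consecutive epochs in the given intensity
set.  "Consecutive" is taken literally: a single epoch outside the set
breaks the run (`bouts.tolerance_epochs = 0`, configurable).  All caps
are inclusive at the boundary, so a day with MVPA exactly 2.5% of wear
adheres.

A participant with no valid prior-stage days gets the configured
fallback baseline (`baseline.fallback`: 120 LPA / 15 MVPA minutes,
deliberately conservative mid-range values for a symptomatic child) and
the result is flagged.

### Participant labels

Two roll-up policies are provided because the source design contains
both: the *any-day* rule (adhered to a stage if at least one valid day
adhered), which is how the headline per-stage counts were produced, and
the a-priori *80% of valid days* criterion (`policy.mode = "fraction"`,
inclusive threshold).  Any-day is the default so that default output
mirrors the headline table; the stricter reading is one switch away.
No valid days in a stage yields "Insufficient data", which is excluded
from denominators but still counted in the per-stage exclusion row, so
adhered + did-not-adhere + excluded always equals the cohort size.

## Self-reported adherence

The subjective criterion in the source design was a judgement by
research personnel -- "has the child been following the guidelines
correctly?" -- anchored to self-reported stage progression with
decreasing symptom scores.  The package replaces the judgement call
with an explicit, auditable proxy: the reported stage sequence must
never regress, and the symptom score (PCSS; 22 items scored 0--6, total
0--132, or a dichotomous 0--22 child form) must end at or below its
first value.  The endpoint comparison, rather than strict monotone
decrease, is the default because symptom scores fluctuate at a 48-hour
cadence; `selfreport.pcss_rule = "monotone"` selects the strict
reading.  Respondents who answer "no" to having had symptoms in the
past two weeks are zero-imputed before labeling.  Adherence is labeled
separately for RTA and RTS; the combined label is "Adhered" only when
both are, the stated convention.

Recovery time is whole days from injury to the verified resolution
date, censored at `selfreport.horizon_days` (180 days, the six-month
follow-up window) when no resolution occurred.

## Statistics

Agreement between objective and self-reported adherence uses the
observed 2×2 table: percent agreement `(a+d)/n` and Cohen's κ
`(p_o − p_e)/(1 − p_e)`.  The confidence interval uses the
Fleiss--Cohen--Everitt large-sample standard error of the estimate and
the test of κ = 0 uses the null-hypothesis standard error; the source
text does not name its interval method, so the standard asymptotic one
was chosen.  Degenerate margins (chance agreement 1) are an error, not
a silent NaN.

On the worked 2×2 example bundled with the package -- cells 16, 36, 8,
24 -- percent agreement is 40/84 ≈ 48% and κ = 4/81 ≈ 0.049.  A
published analysis of this table reports κ = 0.49 with P = .57; that
value is not reproducible from the printed cells (and a κ of 0.49 at
n = 84 could not have P = .57).  The package reports the computed
value and leaves the discrepancy documented rather than reconciled.

Group comparisons use the Mann-Whitney U statistic from rank sums with
midranks for ties.  For pooled sizes ≤ 12 (or on request) the two-sided
p-value is exact: full enumeration of all assignments of the pooled
values to the group sizes, `p = 2 × min(P(U ≤ u), P(U ≥ u))` capped at
1 -- the convention must be stated because tied data make textbook
definitions diverge.  Larger samples use the normal approximation with
tie correction and continuity correction.  Quartiles use the
linear-interpolation convention (`stats::quantile` type 7).  The 0.05
significance convention appears only in reporting, never inside a
computation.

## The synthetic cohort generator

No participant-level data accompany the source design, so the package
ships a generator whose defaults *are* the study conditions: 48-hour
survey cadence; baseline PCSS lognormal with median 36 and IQR 17--56;
per-stage objective adherent fractions 13.3% / 10.8% / 34%; recovery
times lognormal with medians 13 days (self-reported adherent) and 20
days (non-adherent) and a 14% chance of never resolving within the
180-day horizon; reinjury probability 3/139; and self-report labels
that agree with the objective label only at chance
(`selfreport_discordance = 0.5`, matching the near-chance agreement the
study observed).  Stage durations are Poisson-jittered around means of
4/4/5/6/7 days for RTA stages 1--5.

Construction choices that make ground truth exact rather than
probabilistic:

* Counts are drawn uniformly *inside* the intended class's threshold
  band, so every epoch classifies exactly as intended; sedentary draws
  start at 1 count so that true non-wear (exact zeros) is unambiguous.
* Days are assembled from activity blocks (4-min light runs, 2-min
  MVPA runs, and explicit long bouts) separated by sedentary spacers,
  so run structure is known; simulated non-wear gaps are placed inside
  sedentary filler only.
* Each day is built for the stage the scoring engine will assign it --
  the carry-forward of the *reported* stage sequence, including any
  injected regression -- so intended flags are recoverable by
  construction.
* Adherent participant-stages satisfy every clause with a safety
  margin on every day; non-adherent ones carry one explicitly chosen,
  logged violation (e.g. `mvpa_cap`, `bout_count`) on every day of the
  stage, so tests can assert on violation codes and labels are
  recoverable under the default any-day policy.
* Symptom trajectories decay as `S(t) = S0 · 2^(−t/h)` with bounded
  integer noise (± 3), the half-life anchored so the score reaches the
  floor at the drawn resolution day; the resolution-visit survey
  reports symptom-free.
* All randomness flows from one master seed through per-participant
  derived seeds; regenerating a cohort is byte-identical.

What the generator does **not** emulate: physiologic raw acceleration,
device artefacts and spurious spikes, seasonal and school-day activity
structure, and symptom plateaus or relapses.  Passing tests therefore
demonstrate that the pipeline recovers known structure under the stated
statistical conditions -- not that the cut points or rules are valid
measures for any particular real dataset.

## Problem sizes and numerical choices

The test suite exercises the rule engine against a clause-by-clause
brute-force evaluator on 1,000 random days, the exact Mann-Whitney
path against full enumeration on 200 instances of pooled size ≤ 10,
and label recovery on a 200-participant cohort (the package's chosen
standard harness size, where recovery runs at ≈ 99% against a ≥ 95%
requirement; the shortfall is participants whose one-day stage 2 falls
between two 48-hour surveys and is never reported, yielding
"Insufficient data").  The acceptance script regenerates a
150-participant cohort.  Timestamp arithmetic snaps second-level gaps
within 1 microsecond before divisibility checks, POSIXct being
double-based.  Duplicate survey dates keep the last record
(resubmission semantics); days before the first survey inherit its
stage and are flagged.

## Known limitations

* The objective/subjective agreement depends on the self-report proxy;
  a clinician's actual judgement may be systematically more lenient.
* Wear-time bounds, cut points and the non-wear rule are configurable
  but interact: a coarser epoch length weakens bout detection at the
  5-minute boundary.
* Stages 4--6 and RTS have no objective scoring, by design.
* The statistics are unadjusted two-group comparisons; no censoring-
  aware survival modeling is attempted.
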