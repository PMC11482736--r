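# actiadhere

Objective and self-reported adherence to staged pediatric concussion
**Return-to-Activity (RTA)** protocols, scored from waist-worn
accelerometer epoch counts and 48-hour symptom surveys.

After a concussion, children are managed with a six-stage RTA protocol
(and a five-stage Return-to-School protocol) that restricts physical
activity early and reintroduces it gradually. `actiadhere` answers, for
a cohort wearing ActiGraph-style count accelerometers:

* did each participant objectively follow the quantitative rules of RTA
  stages 1–3 on each valid wear day?
* does objective adherence agree with the adherence participants
  self-report (Cohen's κ, percent agreement)?
* do self-reported adherers reach symptom resolution faster
  (Mann-Whitney U on days to resolution)?

## The scoring model

Counts per 30-s epoch are classified by child-calibrated cut points
(sedentary ≤ 50, light ≤ 1147, moderate ≤ 2005, vigorous > 2005 counts
per 30 s; all configurable). Non-wear is removed as ≥ 60-min zero-count
runs unioned with the participant's wear log; a day is valid with
360–1140 min of wear. Per valid day, with `wear`, `LPA`, `MVPA` in
minutes:

| Stage | Rule (all bounds inclusive) |
|---|---|
| 1 | `MVPA ≤ 0.025·wear`; no ≥ 5-min bout at any non-sedentary intensity |
| 2 | `LPA ≤ base₁(LPA) + 30`; `MVPA ≤ base₁(MVPA)`; no ≥ 5-min MVPA bout |
| 3 | `MVPA ≤ base₂(MVPA) + 60`; ≤ 2 MVPA bouts of ≥ 5 min, each ≤ 15 min |

where `baseₛ` is the participant's mean daily minutes over the prior
stage's valid days. A participant "Adhered" to a stage with ≥ 1
adherent valid day (default), or with ≥ 80% adherent days under the
stricter a-priori policy. Self-reported adherence requires a
never-regressing reported stage sequence with a non-rising symptom
score endpoint. See the methods vignette
(`vignettes/adherence-methods.Rmd`) for every convention and why.

## Worked example

```r
library(actiadhere)

# the published-style 2x2 agreement table: self-report vs accelerometer
tab <- contingency_2x2(a = 16, b = 36, c = 8, d = 24)
round(100 * percent_agreement(tab))   # 48  (% of n = 84 in agreement)
round(100 * rate(tab$b, 84))          # 43  (% self-adhered, objective-not)
cohens_kappa(tab)
#> Cohen's kappa: 0.0494 (po = 0.4762, pe = 0.4490)
#> 95% CI [-0.1184, 0.2172], z-test of kappa = 0: p = 0.5698, n = 84

# an end-to-end synthetic study
simulate_cohort(sim_config(n_participants = 20, seed = 1), out_dir = "demo")
res <- run_all("demo", "demo_out")
res$stage_table
#>   stage n_eligible n_adhered n_did_not_adhere n_excluded pct_adhered
#> 1     1         20         1               19          0           5
#> 2     2         20         3               17          0          15
#> 3     3         18         6               12          2          33
```

The stage table mirrors the study-style layout: per stage, how many
participants had scorable data, adhered (≥ 1 adherent valid day), did
not, and were excluded (insufficient wear or survey data) — the three
groups always sum to the cohort size. `demo_out/` also contains the
self-report table, the 2×2 agreement with κ, Mann-Whitney comparisons
of recovery time by self-reported adherence, a structured exclusion
log, and a reproducibility manifest (config snapshot + input hashes);
re-running on the same inputs is byte-identical.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/actiadhere simulate --n 20 --seed 1 --out demo
Rscript inst/scripts/actiadhere run-all --data-dir demo --out-dir demo_out
```

## Input formats

CSV, comma-separated, header row, UTF-8, ISO-8601 local-clock times:

* `epochs/<participant_id>.csv` — `timestamp,counts`
* `wearlog.csv` — `participant_id,start,end,source`
  (`participant_log` | `algorithm`)
* `surveys.csv` — `participant_id,date,pcss_total,pcss_form,rta_stage,
  rts_stage,cognitive_level[,symptom_free]`
* `roster.csv` — `participant_id,injury_datetime,resolution_date,
  reinjured,withdrew`

Counts are assumed to be vertical-axis (matching the cut-point
calibration). Native ActiGraph binary formats (.gt3x/.agd) are out of
scope; export to epoch CSV first.

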