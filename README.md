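# trialcea

Trial-based cost-utility analysis for three-arm randomised trials, built
for within-trial economic evaluations of psychological therapies (two
intensities of an avatar-based therapy for distressing voices versus
treatment as usual, TAU), from a health and social care perspective over
a 28-week horizon.

**Who it is for:** health economists and trial statisticians who need a
reproducible, tested pipeline from participant-level service-use records
to publication-style cost-effectiveness outputs — and a calibrated
synthetic-trial generator so every stage can be exercised when the real
participant-level data are access-restricted.

## What it computes

* **Costing** — CSRI-style service contacts and in-patient days valued at
  per-contact / per-diem unit costs (GBP 2021/22), plus the therapy cost:
  sessions × £82.37 (Band 8 rate with a 51% non-contact uplift) + a £50
  fixed technology cost per recipient.
* **QALYs** — EQ-5D-5L profiles valued through a pluggable 3,125-state
  value set (the shipped default is a synthetic crosswalk-style set
  anchored at 1 and −0.594), combined by the area-under-the-curve
  trapezoid over weeks 0/16/28:
  `Q = (u0+u16)/2 · 16/52 + (u16+u28)/2 · 12/52`.
* **Incremental estimates** — multiple imputation by chained equations
  with predictive-mean matching (5 donors), a seemingly unrelated
  regression of follow-up cost and QALYs on arm, baseline cost/utility
  and site, Rubin pooling, and dominance/ICER classification
  (`ICER = ΔC/ΔQ`).
* **Uncertainty** — the imputation nested inside an arm-stratified
  bootstrap; cost-effectiveness planes and acceptability curves
  (probability the therapy has the highest net benefit `λ·ΔQ − ΔC`) over
  λ = £0–£100,000 in £2,000 steps.
* **Sensitivity** — deterministic scenarios on the fixed technology cost
  (£25–£150) and therapist cost (±25%, ±50%), plus an available-case OLS
  route.

## Worked example

```r
library(trialcea)

cfg    <- synth_config()                          # trial-calibrated defaults
bundle <- generate_trial(cfg, seed = 1) |>
  impose_missingness(cfg, seed = 1)               # MAR follow-up, ~10-25%

res <- run_pipeline(bundle, m = 10, B = 1000, seed = 1)
res
```

```
Cost-utility analysis result
  participants: 345 
  BRF_vs_TAU: dC = 1582 GBP (-230 to 3395), dQ = 0.0209 (0.0061 to 0.0357), ICER = 75575 GBP/QALY
  EXT_vs_TAU: dC = 805 GBP (-637 to 2248), dQ = 0.0176 (-0.0002 to 0.0355), ICER = 45665 GBP/QALY
  P(AV-BRF most cost-effective at 20000 GBP/QALY) = 0.079
  P(AV-EXT most cost-effective at 20000 GBP/QALY) = 0.174
```

Reading the output: on this synthetic replicate both therapy arms add a
small number of QALYs (~0.02 of a year) at extra cost, putting each in
the trade-off quadrant with an ICER of `ΔC/ΔQ` well above a
£20,000/QALY threshold — hence the low acceptability probabilities,
which count how often each therapy had the higher net benefit
`λ·ΔQ − ΔC` across the 1,000 bootstrap resamples. Had a replicate shown
cost savings with a QALY gain the line would instead read `dominant`
and report no ICER. Single replicates vary widely: cost CIs spanning
thousands of pounds are the expected behaviour when a handful of long
psychiatric admissions dominates total cost (the generator's mean
incremental cost is about −£200 against this replicate's +£1,582).

`write_results_tables(res, "results/")` emits `incrementals.csv`,
`ceac.csv`, per-comparison plane CSVs, `quadrants.csv`,
`sensitivity.csv`, `costs_summary.csv` and a run log;
`autoplot(res$draws)` and `autoplot(res$ceac)` draw the plane and the
acceptability curves. Fitted objects support `tidy()` and `glance()`.

Real data enter through five CSVs (`roster.csv`, `service_use.csv`,
`therapy.csv`, `eq5d.csv`, optional `assessments.csv`) read by
`read_trial_bundle()`, with unit costs from `load_unit_costs()`. A thin
command-line wrapper lives at `inst/scripts/cea.R`
(`cea.R synth`, `cea.R run`).

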