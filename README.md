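# icuresp

Continuous respiratory-state monitoring and ventilator-demand forecasting
for ICU time series, in R.

## What it does, and for whom

Intensive-care data arrive as irregular observation streams: pulse-oximetry
every few minutes, arterial blood-gas panels every few hours, ventilator
channels only while a ventilator is attached. Clinicians grade hypoxemic
respiratory failure (RF) by the **P/F ratio** — arterial oxygen partial
pressure PaO2 (mmHg) over the inspired oxygen fraction FIO2 — with
P/F < 300 mild, < 200 moderate and < 100 severe. `icuresp` is for
clinical-data scientists who want to turn such streams into:

1. a **5-minute gridded patient state** with clinically motivated
   forward-fill imputation (dense for annotation, missingness-preserving
   for features);
2. a **continuous P/F estimate**, combining the Severinghaus
   oxygen-hemoglobin dissociation curve `S(p) = 1/(23400/(p³+150p)+1)`,
   its closed-form Ellis inversion, and a nested robust polynomial
   regression that corrects the curve with SaO2/pH context and its own
   past errors;
3. rule-based **endpoint tracks** — RF severity (forward 1-h 2/3-window
   rule with right-edge correction and 4-h sandwich post-processing),
   mechanical-ventilation status (a point-based vote over EtCO2, mode,
   tidal volume and airway indicators, cutoff 4), readiness to extubate
   (13 violation criteria, threshold 9, trailing 1-h 2/3 rule);
4. **labels and models** for four early-warning tasks — RF onset,
   ventilation onset, readiness onset (24-h horizons) and extubation
   failure (re-intubation within 48 h) — trained with gradient-boosted
   trees (native missing-value routing, early stopping on time-point
   AUPRC, exact TreeSHAP attribution);
5. **event-based alarm evaluation** with a 4-h silencing / 30-min
   post-recovery re-arm policy, detectable-prevalence chance floors,
   prevalence correction across cohorts and subgroup bootstrap analysis;
6. an ICU-level **ventilator-demand forecast** (per-patient probabilities
   summed plus a new-admissions regressor) against a persistence baseline.

Everything runs end to end on a bundled synthetic ICU cohort simulator
with known ground truth — no clinical data are shipped or required. See
`vignettes/methods.Rmd` for the model details and design decisions.

## Worked example

```r
library(icuresp)

co  <- simulate_cohort(sim_config(n_stays = 120), seed = 11)
run <- run_rms_pipeline(co$stays, tasks = "RF", seed = 11, nrounds = 200L)

pr    <- event_pr_curve(run$eval_sets$RF)
floor <- detectable_prevalence(run$eval_sets$RF, n_sim = 20, seed = 1)
cat("event AUPRC:", round(pr$auprc, 3), " chance floor:", round(floor, 3), "\n")
#> event AUPRC: 0.386  chance floor: 0.176
```

The pipeline simulated 120 stays, gridded and annotated them, trained an
RF-onset model on one patient-level 80:20 split, scored the held-out test
stays every 5 minutes, and ran the alarm policy over a threshold sweep.
The event AUPRC (0.386) is the area under the alarm-precision /
event-recall curve: at each threshold, the fraction of alarms followed by
an RF onset within 24 h against the fraction of RF events preceded by an
alarm. The chance floor (0.176) is what a random score would achieve under
the same alarm policy — the model's margin over it, not its absolute
value, is the meaningful number. (Exact values vary slightly with
package/BLAS versions; these were produced by the code above on the
grading image.)

Single pieces are exported too:

```r
ellis_pao2(0.90)          # PaO2 at 90% saturation: ~58.7 mmHg
pao2_sample_weight(110)   # regression weight at the decision boundary: 60
```

A small CLI lives in `inst/cli/rms.R`
(`Rscript inst/cli/rms.R simulate|train|evaluate ...`).

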