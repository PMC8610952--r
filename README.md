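# oliguard

Early warning of severe acute kidney injury (AKI) from urine-output trends
in intensive-care patients.

Severe AKI — AKIN/KDIGO stage 2 or 3 — is common in the ICU and carries high
mortality, yet it is typically recognised only once the diagnostic criteria
are already met. Because oliguria usually precedes the creatinine rise, the
hourly urine-output trend contains an early signal. `oliguard` implements a
complete, testable pipeline that turns raw nursing-charted urine output and
creatinine labs into an hourly 0–100 risk score that leads the diagnosis by
at least six hours, for biostatisticians and critical-care data scientists
who want to study or re-train such scores without access to restricted
clinical databases.

## What it computes

**Endpoint.** A stay is a *case* when the joint AKIN stage-2/3 criteria are
met: creatinine at 200–300% of the baseline (the lowest ICU value) together
with urine output < 0.5 ml/kg/h for > 12 h (stage 2); creatinine > 300% of
baseline, or ≥ 4.0 mg/dl with an acute rise ≥ 0.5 mg/dl, together with
urine output < 0.3 ml/kg/h for > 24 h or anuria > 12 h (stage 3). Onset is
the first hour at which the completed oliguria duration and the creatinine
clause hold jointly. Case series are truncated 6 h before onset, so every
prediction leads the event.

**Preprocessing.** Urine output is resampled to an hourly grid: a volume
charted after a gap of *k* hours (*k* ≤ 9) is spread uniformly, `volume/k`
per hour, conserving total volume exactly; creatinine is dragged forward to
the next measurement when the gap is under 4 days. Flows are normalised to
ideal body weight by Devine's formula (50 kg male / 45.5 kg female + 2.3 kg
per inch over 60 in). Stays with LOS < 24 h, baseline creatinine
< 0.5 mg/dl, community-acquired AKI, dialysis, longer charting gaps, or
low-volume centers are excluded.

**Models.**

* *Logistic:* 11 features per prediction hour `t` — for each window size
  `w ∈ [2, 12]`, `f_w(t) = min_s mean(uo[s .. s+w))` over windows inside
  `[0, t)` — fed to a maximum-likelihood logistic regression (one randomly
  sampled prediction hour per patient), or a single-feature threshold rule
  (the published rule alarms when the 7-h minimum moving average falls
  below 0.372 ml/kg/h).
* *Convolutional:* a compact 1-D CNN (stacked blocks of parallel kernels
  3/5/7 with highway gates, global average pooling, sigmoid head; ~5k
  parameters, written in dependency-free vectorised R with hand-derived
  backpropagation) maps each 12-h urine-output window to a probability,
  Platt-calibrated and scaled to an hourly 0–100 score; a score at hour `t`
  refers to onset risk at or after `t + 6`.

**Evaluation.** Patient-disjoint 60/10/20/10 train/validation/test/
calibration splits; ROC/AUC (tie-corrected Mann–Whitney); operating points
at fixed 80% sensitivity and at the ROC knee (nearest point to perfect
sensitivity and specificity); likelihood ratios LR+ = sens/(1−spec),
LR− = (1−sens)/spec; resampled mean ± SD; fraction of cases alarmed at
least 12 h before onset; per-stage breakdown.

**Synthetic cohorts.** A seeded generator emulates the statistical structure
the analysis assumes — irregular charting, ~3% stage-2/3 prevalence,
injectable episodes that satisfy the joint criteria at a requested onset,
controls with transient (< 12 h) oliguric dips — so every stage is testable
without credentialed data.

## Worked example

```r
library(oliguard)
cfg <- cohort_config(n_patients = 400, prevalence = 0.1, noise_sd = 0.15,
                     control_dip_rate = 0.1, los_hours_range = c(48, 120),
                     seed = 7)
report <- run_pipeline(pipeline_config(cohort_config = cfg,
                                       model = "logistic_multi",
                                       n_resamples = 50, seed = 7))
print(report)
```

```
[simulate] generating synthetic cohort (n=400, seed=7)
[preprocess] 400 stays in, 400 kept, 0 excluded ()
[label] 33 cases (stage 2: 21, stage 3: 12), 367 controls
[split] calibration=40, test=80, train=240, validation=40
[train] multi-feature logistic on 240 patients
[evaluate] test AUC 0.960 (resampled 0.959 +/- 0.011), knee sens 1.00 spec 0.94, early detection 25%
<uo_report> model logistic_multi: 80 test patients (8 cases)
  AUC 0.960 (resampled 0.959 +/- 0.011)
  knee: sens 1.00 spec 0.94 LR+ 18.00 LR- 0.00
  fixed 80%: sens 1.00 spec 0.94 LR+ 18.00 LR- 0.00
  early detection (>= 12 h lead): 25%
```

Reading the output: the labeler found 33 stage-2/3 episodes (8.2%); the
held-out AUC of 0.960 says a random case outranks a random control 96% of
the time; at the knee-point threshold all 8 test cases alarm while 94% of
controls stay silent (LR+ 18 — an alarm multiplies the odds of AKI
eighteen-fold); 25% of the cases alarmed at least 12 h before they met the
diagnostic criteria (every alarm here leads by at least 6 h by
construction). At this cohort's low noise the logistic model is already
strong; `model = "cnn"` trains the convolutional score instead.

A shell entry point wraps the same functions:

```sh
Rscript scripts/run_pipeline.R run-all --n 2000 --model cnn --seed 1 --out-dir runs/demo
```

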