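---
title: "Methods: urine-output-based early warning of severe AKI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urine-output-based early warning of severe AKI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliguard)
```

# The problem and the endpoint

Severe acute kidney injury in the ICU is staged by the AKIN/KDIGO criteria
from two signals: a relative rise of serum creatinine over the patient's
baseline, and sustained oliguria. `oliguard` targets the *joint* stage-2/3
endpoint:

* **stage 2** — creatinine at 200–300% of baseline *and* urine output
  below 0.5 ml/kg/h for more than 12 h;
* **stage 3** — creatinine above 300% of baseline, or at least 4.0 mg/dl
  with an acute rise of at least 0.5 mg/dl, *and* urine output below
  0.3 ml/kg/h for more than 24 h or anuria for more than 12 h.

All durations are strict: exactly 12 hours below threshold does not
qualify. The baseline is the lowest creatinine reported during the
patient's ICU course (minimum across stays for re-admitted patients).
Requiring both clauses makes the endpoint specific but leaves two timing
questions the criteria themselves do not answer; our choices are:

* **Coupling window.** The creatinine clause may be met at any hour inside
  the oliguria window or within 24 h after it ends
  (`scr_coupling_hours`, configurable). Laboratory draws are sparse
  relative to hourly urine charting, so demanding the two clauses at the
  same clock hour would miss episodes purely through lab latency; a day is
  a lab-cycle-scale tolerance.
* **Onset anchoring.** Onset is the first hour at which the completed
  urine-output duration and the creatinine clause hold jointly — the first
  hour the diagnostic criteria are actually met, which is the reference
  against which prediction lead times are measured. When stage-2 and
  stage-3 criteria complete at the same hour, stage 3 wins; otherwise the
  earlier onset wins. A creatinine ratio of exactly 300% is assigned to
  stage 2 (the stage-3 clause is strictly "above 300%"). Anuria is
  urine output at or below 1e-9 ml/kg/h — numerical zero, so that
  redistribution round-off cannot mask it.

The "acute rise ≥ 0.5 mg/dl" for the absolute stage-3 clause is evaluated
against the running minimum over the previous 48 h, the usual convention
for acuteness.

# Preprocessing

Nursing-charted urine output is irregular. Each charted volume covers the
interval since the previous record (or admission); we spread it uniformly
over that interval and attribute it to 0-based hour bins `[h, h+1)` by
overlap fraction. This conserves charted volume exactly (the package
asserts relative error below 1e-9), is idempotent on already-hourly data,
and needs no model of within-gap kinetics. Gaps longer than 9 h are *not*
filled: the affected hours stay missing and the stay is flagged for
exclusion — silently imputing a long gap would manufacture oliguria or
hide it. The limits are strict ("more than 9 h", "more than 4 days"),
matching the exclusion rules' wording.

Creatinine is forward-dragged: each hour carries the most recent
measurement; hours before the first draw carry it backwards (flagged
imputed). Flows are normalised by ideal body weight (Devine: 50 kg male /
45.5 kg female + 2.3 kg per inch over 60 in, 2.54 cm/in exactly). Heights
below 60 in return the base weight: the formula is undefined there, and
extrapolating downward would inflate per-kg flows for short patients.

Exclusions mirror a multi-center retrospective design: LOS < 24 h,
baseline creatinine < 0.5 mg/dl, community-acquired AKI, dialysis (a
pass-through metadata flag; treatment records are out of scope), charting
gaps > 9 h, creatinine gaps > 4 days, centers below 50 admissions in the
input cohort. "Community-acquired" is not defined by the staging criteria;
we operationalise it as the joint criteria completing within the first
12 h of the stay (`ca_horizon_hours`) — such an event precedes any
possible 12-h-lookback prediction, so it is prevalent rather than
ICU-acquired from the model's point of view. Every triggering reason is
reported; the waterfall accounting (each excluded stay counted once under
its first reason) is asserted by the pipeline.

# Models

## Sliding-window logistic models

At prediction hour `t ≥ 12`, feature `f_w(t)` is the minimum over all
length-`w` windows inside `[0, t)` of the mean urine output, for
`w = 2 … 12` — eleven numbers summarising the worst sustained diuresis at
every time scale up to half a day. They are computed in O(n) per window
size via running minima of the moving averages, and the implementation is
tested for exact agreement with an exhaustive scan. Control stays
contribute a feature vector at every eligible hour, case stays at every
hour of their truncated series; one vector per patient is then drawn
uniformly (seeded) so that fitted samples are independent across patients.
The multi-feature model is a plain maximum-likelihood logistic regression
(no penalty; an L2 switch exists for separable toy data). The
single-feature variant is a fixed threshold rule on one `f_w`; the
published rule (7-h window, 0.372 ml/kg/h, strict inequality) ships as a
constant, and thresholds can be re-derived on synthetic calibration data.

## Convolutional risk score

The deep model maps each 12-h urine-output window to the probability of
meeting the diagnostic criteria from 6 h onward, updated hourly and scaled
to 0–100; scores above the alarm threshold (default 70) raise an alarm.
Case series are truncated 6 h before onset and every window of a truncated
case is labelled positive — the case/control label is a property of the
stay, and which pre-onset windows are "informative" is exactly what the
network should learn; a horizon-limited labelling (positives only within
`horizon_hours` of onset) is available as a switch. Onsets before hour 19
leave no room for one 12-h window plus the 6-h lead and are dropped with a
logged reason.

The architecture is two stacked blocks, each with parallel 1-D
convolution branches (kernels 3, 5, 7 — sub-half-day motifs at three
scales) concatenated to 24 channels, a highway gate blending the block's
ReLU output with a linear projection of its input, then global average
pooling and a sigmoid head: about 5,000 parameters. These hyperparameters
are deliberately small — the input is 12 numbers, and desk-scale CPU
training is a design goal — and all are exposed in `model_config()`.
Forward pass and backpropagation are written in vectorised base R
(activations as `(n·T) × C` matrices; convolutions as sums of time-shifted
matrix products); gradients are verified against numerical differentiation
in the test suite.

Training: Adam (default learning rate 3e-3, batch 256, up to 12 epochs,
at most 40,000 windows per epoch), inverse-prevalence class weights (cases
are ~3% of patients and fewer of windows), early stopping on validation
AUC with patience 3. Ties in validation AUC count as improvement so that
among equally discriminating checkpoints the later, sharper-probability
weights are kept. Everything is seeded; two runs with the same seed are
identical.

Calibration is Platt scaling on the held-out calibration split: a
logistic regression of the outcome on the raw logit. It is monotone for
positive slope (a non-positive slope triggers a warning), hence
rank-preserving — ROC and AUC are unchanged — while the expected
calibration error improves on miscalibrated scores.

# Evaluation protocol

Patients are partitioned 60/10/20/10 into training, validation, test and
calibration sets (seeded; counts within one patient of the targets;
disjointness asserted on every run). Headline metrics are patient-level: a
case counts as detected if any pre-onset score exceeds the threshold, a
control as a false positive if any of its scores does — the clinically
relevant reading of a continuously updated alarm. AUC is the tie-corrected
normalised Mann–Whitney statistic (exact against pair counting in tests).
Two operating points are reported: the best-specificity point reaching 80%
sensitivity, and the knee-point, defined as the ROC vertex of minimal
Euclidean distance to perfect sensitivity and specificity (ties toward
higher sensitivity; Youden's J is available by flag). Likelihood ratios
follow from the reported sensitivity/specificity; at specificity 1 the
positive ratio is reported infinite with a flag. Test-set variability is
summarised as mean ± SD of AUC over seeded 80% patient subsamples
(degenerate single-class resamples are redrawn and counted). The
early-detection fraction is the share of cases whose first alarm precedes
onset by at least 12 h, with silent cases counted as misses; it is monotone
non-increasing in the required lead.

Alarm thresholds near 70 on the 0–100 scale are meaningful only relative
to a particular calibration; the evaluation therefore re-derives its
operating thresholds per run rather than shipping fitted constants.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's guarantees are stated.

* Controls draw a per-patient baseline diuresis from a lognormal (median
  1.1 ml/kg/h, sdlog 0.35 between patients) with multiplicative lognormal
  hourly noise (sdlog 0.35) — positive, right-skewed, two parameters —
  yielding a right-skewed distribution of per-stay minimum diuresis in the
  0.3 ml/kg/h region. 30% of controls contain a transient oliguric dip
  (3–10 h, 0.15–0.45 ml/kg/h), shorter than every AKIN duration, so the
  labeler is genuinely exercised rather than trivially negative.
* Charting gaps are geometric-like with mean 2 h, truncated at 8 h so
  default cohorts survive the 9-h exclusion; `allow_long_gaps` mixes in
  10–14 h gaps to exercise it. Creatinine is drawn roughly daily, with
  extra draws during an injected episode (labs are ordered more often when
  a patient deteriorates); at `noise_sd = 0` trajectories are fully
  deterministic.
* Injected episodes place the oliguric phase so its required duration
  completes exactly at the requested onset (≥ hour 30 by default, leaving
  the 12-h lookback plus 6-h lead), with the creatinine ramp crossing the
  stage multiplier — relative to the realized pre-episode minimum — shortly
  after oliguria begins. The criteria constrain only the endpoint, not the
  shape, so the ramp is smooth for stage 2 and a step for stage 3 (the
  step skips the 200–300% band between consecutive draws, preventing a
  spurious earlier stage-2 call). Oliguric-phase hours are clamped below
  the stage threshold after noise, and pre/post-episode hours are kept
  above 0.55 ml/kg/h, because an injected case must satisfy its criteria
  at the requested onset by construction; heights are 150–195 cm, ~63%
  male.
* At noise-free, gap-free settings the round trip is exact: injected
  episodes are recovered with the injected stage and onset (±1 h), and
  constructed controls are never labelled — both asserted on hundreds of
  stays in the test suite.

What the generator does **not** emulate: fluid therapy, vasopressors and
diuretics (which decouple urine output from renal function), dialysis
dynamics, inter-hour autocorrelation beyond the injected phases, circadian
charting patterns, and the marginal distributions of any real cohort. A
passing pipeline here shows the machinery is correct and that a detectable
oliguric signal is detected; it says nothing about discrimination on real
ICU data.

`separable_cohort_config()` is a preset for the constructed-signal
benchmark: low-noise controls near 1 ml/kg/h without dips, stage-3 cases
with a long sustained 0.15 ml/kg/h phase — window populations of cases and
controls are cleanly separable, so the convolutional model is expected to
approach AUC 1 and to match or beat the single-feature rule.

## The permutation null

The null benchmark retrains the network under a window-label permutation
spanning training, validation *and* test, and measures held-out AUC
against the permuted labels, expecting ~0.5. Two subtler designs fail for
instructive reasons: permuting only training labels lets checkpoint
selection on a true-labelled validation set pick whichever random drift
happens to align with urine output (an information leak); and evaluating a
label-blind model against *true* test labels is unstable on a separable
cohort, because any chance tilt of its scores along the urine-output axis
moves the AUC far from 0.5. Permuting end to end breaks the
label–trajectory link everywhere and concentrates the null where it
belongs.

# Numerical choices and degenerate inputs

* Strict inequalities throughout: oliguria is `< threshold`, durations are
  `> 12/24 h`, the single-feature rule alarms `< 0.372`, alarms are
  `score > threshold`.
* Volume redistribution tolerates sub-hour record times (pro-rated by
  overlap); hours never covered by a record are missing, break oliguria
  runs, and exclude their windows from feature/sample construction.
* A stay with no creatinine at all is flagged for exclusion rather than
  guessed; a baseline cannot be computed from an empty record.
* Logistic fits on separable data produce the usual glm warnings;
  `regularize = TRUE` (ridge) is the documented escape hatch.
* Single-class training, validation or calibration data raise errors
  naming the degenerate split; single-class resamples are redrawn with a
  logged count.
* Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logits in Platt
  scaling; risk scores are clamped to `[0, 100]`.

# Problem sizes

The shipped tests and the acceptance script run, per invocation: a
2,000-patient separable benchmark with two network trainings (at most
40,000 windows per epoch, 8 epochs); a 500-case noise-free round-trip plus
1,000 constructed controls; volume conservation on 1,000 random stays; and
oracle comparisons on series up to 200 h. These sizes were chosen so a
complete run takes a few minutes on one CPU while keeping every binomial
check comfortably powered.

# Known limitations

* The CNN is trained with a fixed small architecture; no hyperparameter
  search is performed or supported beyond `model_config()`.
* Stage-1 AKI, creatinine-only and urine-output-only definitions, and
  dialysis-requiring AKI are out of scope.
* Window-level and patient-level metrics answer different questions; the
  package reports patient-level headlines and exposes window-level samples,
  without adjudicating between them.
* The generator's distributional shapes are stand-ins chosen for
  plausibility, not estimates of any real ICU population; conclusions
  about real-data performance require real data.
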