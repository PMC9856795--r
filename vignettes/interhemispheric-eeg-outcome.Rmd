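---
title: "Interhemispheric EEG asymmetry and hemispherotomy outcome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric EEG asymmetry and hemispherotomy outcome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

## The problem

Hemispherotomy — the surgical disconnection of one cerebral hemisphere —
stops seizures in roughly 50–90% of children with drug-resistant
hemispheric epilepsy, but a substantial minority relapse even after
radiologically complete disconnection. One candidate explanation is that in
relapsing patients the epileptogenic hemisphere is more strongly coupled to
its healthy counterpart before surgery. This package operationalizes that
hypothesis on routine presurgical scalp EEG: it quantifies
*interhemispheric asymmetry* of standard spectral and time-domain features
over homologous 10–20 electrode pairs and asks whether a small feed-forward
network can separate seizure-free (SF, Engel IA) from non-seizure-free
(NSF) patients from those asymmetries alone.

The cohort the pipeline is designed around is small and fixed: 21 pediatric
patients, 15 of whom (71%) were seizure- and drug-free at a median
follow-up of 5.1 years. The bundled table (`study_cohort()`) carries their
age at surgery, etiology, histology, Engel outcome and follow-up. The SF
class is Engel IA *exactly*; all other grades (ID, II, III, IV) are NSF,
which reproduces the 15/6 split. Note one internal inconsistency of the
source table we deliberately do not repair: the narrative histology counts
("gliosis/inflammatory infiltrates in 11") cannot be reconstructed from the
row-level histology entries (9 gliosis + 6 inflammatory); `cohort_summary()`
reports raw row counts.

## Signal pipeline

**Recordings.** 19-channel 10–20 scalp EEG, 256 Hz, monopolar against G2,
stored as 16-bit EDF with a JSON sidecar naming the pathological hemisphere
and one expert-selected 60-s wake and one 60-s sleep-stage-II segment. The
reader maps modern temporal-chain labels (T7/T8/P7/P8) onto the legacy
names (T3/T4/T5/T6) used throughout. Signals are used against the recording
reference; no re-referencing is applied.

**Filtering.** 0.5–45 Hz 4th-order Butterworth band-pass. Two numerical
choices matter here. First, the filter is realized as cascaded second-order
sections: at a 0.5 Hz corner and 256 Hz sampling the poles of the order-8
transfer-function form sit close enough to the unit circle that direct-form
filtering loses ~3 decimal digits (measured linearity error ~7e-9 relative,
vs ~3e-12 for the cascade). Second, filtering is zero-phase
(forward–backward) by default, which squares the magnitude response and
removes phase distortion; a `single_pass` mode gives the literal causal
4th-order filter. Since the same filter is applied to every channel, phase
handling cannot bias left–right differences either way; zero-phase is
preferred so that windowed features are not contaminated by group delay.
The *full* recording is filtered before segments are cut, so window edges
are interior samples and carry no filter transient.

**Windowing.** Each 60-s segment is cut into contiguous, non-overlapping
5-s windows; a trailing partial window is dropped. 60 s at any integer-
compatible rate gives 12 windows; concatenating them reproduces the
filtered segment exactly.

## Features

Nine features per electrode per window — six spectral, three temporal:

* **Band powers.** One-sided modified periodogram of the 5-s window with a
  symmetric Hann taper (frequency resolution 0.2 Hz at 256 Hz), integrated
  with half-open `[lo, hi)` bin assignment over delta 0.5–4, theta 4–8,
  alpha 8–13, beta 13–30, gamma 30–45, and total 0.5–45 Hz. The source
  protocol does not name band edges or the estimator; these are declared
  choices. A single periodogram per window (rather than Welch sub-averaging)
  is used because the 5-s window *is* the analysis unit. Half-open bands
  tiling the acquisition range make the five narrow-band powers sum exactly
  to the total-band power of the same estimate — a property the tests
  assert at 1e-6 relative, alongside agreement with a naive DFT-bin
  summation oracle. The symmetric (rather than periodic) Hann taper makes
  every feature exactly invariant under time reversal of the window.
* **Hjorth parameters.** Activity = population variance (µV²); mobility =
  `sqrt(var(diff(x))/var(x))`, per-sample convention without sampling-
  interval scaling (any consistent scaling cancels in complexity and in
  left–right differences); complexity = mobility of the first difference
  over mobility of the signal (1 for a pure sinusoid, >1 for noise).
  Zero-variance windows return 0 for mobility/complexity with a warning
  instead of propagating NaN.

Midline electrodes (Fz, Cz, Pz) are excluded; the 16 lateral electrodes ×
9 features give 144 values per EEG segment and, after averaging each
feature over the 12 windows, a 288-value per-patient tensor
(9 × 16 × 2 states).

## Lateralization and the four datasets

For each of the 8 homologous pairs (Fp1/Fp2 … O1/O2), each state and each
feature, the classifier input is the value at the pathological-hemisphere
electrode minus the value at its healthy homolog — sign convention fixed as
pathological − healthy, so swapping the declared side negates every
difference. Per-pair differencing (rather than whole-hemisphere averaging)
preserves topography; the source text supports both readings and the
per-pair one is used because it retains strictly more information. The
network consumes these 144 differences (9 × 8 × 2); the 288-value tensor is
the intermediate. For sensitivity analyses, `build_input_matrix()` also
offers a `hemisphere_mean` mode (difference of whole-hemisphere feature
means, 18 inputs) and a `raw` mode (the undifferenced 288-value tensor),
and `rereference_car()` applies a common-average reference — homologous
differences themselves are reference-invariant, so the default keeps the
recording reference.

Four nested-ish feature subsets mirror the study's selection step:

1. all nine features — 144 columns;
2. total-band features only (total power + broadband Hjorth) — 64 columns;
3. PSD features for every band — 96 columns;
4. Hjorth parameters for every band — 288 columns, computed by re-filtering
   the signal into each band *before* windowing and recomputing Hjorth
   (the only reading consistent with "for every band"; the broadband
   Hjorth values serve as the total-band entries).

Dataset 4's band-filtered Hjorth features are not among dataset 1's
columns, so the subset relation holds for datasets 2 and 3 only — an
unavoidable consequence of reading dataset 4 as band-filtered. Columns are
z-scored with training-fold statistics only.

## Classifier and evaluation protocol

Nine fully connected topologies — hidden layers [8], [8,8], [5], [5,5],
[4], [4,4], [3], [3,3], [2] — with tanh hidden units, a single sigmoid
output, MSE loss, full-batch gradient descent with a multiplicative
adaptive step (×1.05 after an improving epoch; ×0.5 with rollback after a
worsening one, a "bold driver" schedule) and early stopping on validation
MSE (patience 6, epoch budget 300). This mirrors the contract of the
original MATLAB defaults (gradient training, MSE, validation stop) without
reproducing any toolbox internals. With ≤8-neuron layers and ≤30 training
patients, training is effectively instantaneous, so no stochastic
mini-batching is needed and runs are bit-reproducible under a fixed RNG
seed.

Each architecture is trained 20 times on random 70/15/15
train/validation/test partitions *at patient level* (n = 21 resolves to
15/3/3 by largest-remainder rounding). Splits are label-stratified by
default: with only 6 NSF patients, unstratified 15-patient training folds
can lack the NSF class entirely; a `stratify = FALSE` mode gives the
literal fully-random protocol. Reported per architecture:

* the mean over iterations of the column-normalized (per true class)
  2 × 2 confusion matrix;
* **P**, the mean overall test accuracy (%) ± SD. The source's description
  ("mean of the diagonal of the confusion matrices") applied to its own
  printed matrix gives 62.5%, not the printed 73.3%; prevalence-weighted
  accuracy does match, so P is defined as plain test accuracy, and the
  diagonal mean (balanced accuracy) is reported alongside as `diag_mean`;
* SF recall and NSF recall ± SD, labelled explicitly rather than as
  sensitivity/specificity (the source's class assignment for those terms is
  internally inconsistent between its tables);
* held-out output MSE (mean squared deviation of the sigmoid output from
  the 0/1 target, in %), the dataset-selection criterion; the test
  misclassification rate is reported alongside since the source's MSE
  definition is not stated.

Architecture selection maximizes P, breaking ties by lower SD, then fewer
trainable parameters (the proxy for "fastest").

## Synthetic cohort generator

Real recordings are not deposited, so the generator produces cohorts with
exactly the statistical structure the analysis assumes:

* per state, band-limited oscillations from 5 random-phase sinusoids per
  band (amplitudes analytically controllable: band RMS² = target band
  power), with wake alpha posterior-dominant and sleep delta/theta-
  dominant; oscillator frequencies are drawn 0.5 Hz inside band edges so
  spectral mass stays in-band and inside the acquisition filter passband;
* 1/f^0.7-shaped Gaussian background noise (default 2 µV RMS);
* lognormal amplitude jitter per patient × state × band (sdlog 0.2) and
  per channel (sdlog 0.1);
* a pathological-hemisphere perturbation multiplying band amplitudes by
  (delta 1.5, theta 1.3, alpha 0.6, beta 0.8, gamma 1.0) — focal slowing
  with alpha suppression, affecting both spectral features and, through
  the shifted spectral centroid, Hjorth mobility/complexity;
* the class mechanism: SF patients express the full asymmetry; NSF
  patients' factors are shrunk toward symmetry by the effect size
  `effect_delta` (`f_NSF = 1 + (f − 1)(1 − δ)`) — "healthier-looking"
  contralateral coupling of the pathological rhythm, i.e. higher
  interhemispheric connectivity predicting recurrence. At δ = 0 the
  classes are exchangeable by construction; δ = 1 makes NSF patients
  symmetric. The default δ = 0.5 sits mid-scale. Because the generator's
  variability model is deliberately low-dimensional (amplitude jitter plus
  stationary noise; no artifacts, no per-patient topography differences),
  even mid-scale effects are highly separable at n = 21 — desk-scale runs
  of the analysis scripts classify nearly perfectly, unlike real cohorts.
  Chance-level behaviour is reached as δ → 0; the recovery studies use
  δ = 1.

What the generator does **not** emulate: volume conduction and a forward
head model, artifacts (the protocol applies no artifact suppression),
epileptiform transients, non-stationarity within segments, and any
correlation between EEG asymmetry and the clinical covariates. Passing
recovery tests therefore show that *the pipeline recovers the kind of
signal it assumes*, not that real presurgical EEG carries that signal.

## Study sizes and numerical conventions

The calibration and recovery studies in the test-suite and acceptance
script run at sizes chosen to keep a full desk-scale replication cheap
while leaving the statistical conclusions unambiguous: permutation-null
calibration on one balanced 14-patient cohort over 50 label-permutation
seeds (5 iterations each), monotonicity of recovery over δ ∈ {0, ⅓, ⅔, 1}
with 3 generator seeds per point, strong-signal recovery at n = 42 with
the full 20 iterations, and feature-subset comparison on 21 patients with
10 iterations. Decision threshold on the sigmoid output is 0.5
(configurable). Confusion-matrix columns with no true-class member in an
iteration are excluded from that iteration's normalized average rather
than imputed.

## Known limitations

* The per-band Hjorth reading of dataset 4 triples its width (288 columns
  for ~15 training patients); with the original data this subset would be
  the most overfit-prone, which its relatively poor held-out MSE reflects.
* The headline clinical numbers (73.3% accuracy, 85%/40% class recalls)
  are not reproducible without the undeposited recordings; the package
  replaces them with structural and synthetic-recovery checks, and no
  claim about real-EEG predictive power is made.
* Stratified splitting departs from the literal "random" protocol to keep
  every training fold two-class; the literal mode is available.
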