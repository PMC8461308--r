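---
title: "Quantifying EMS suppression of parkinsonian tremor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMS suppression of parkinsonian tremor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorglove)
```

## The problem

Resting tremor in Parkinson's disease is a 4-6 Hz oscillation that surface
electrical muscle stimulation (EMS) of the hand muscles can transiently
suppress. A sensing glove with a 3-axis wrist gyroscope measures the tremor
while an EMS module stimulates; the clinically interesting quantity is the
**tremor reset time**: how long the tremor stays reduced, counting both the
reduction achieved during stimulation and its persistence after the
stimulator is switched off. `tremorglove` implements the full analysis
stack around that quantity — signal featurization, session metrics, a
multiclass stimulation-level predictor suite, a closed-loop controller
simulation — together with a virtual-patient generator, because the
underlying clinical recordings are not publicly available.

## The virtual patient and session simulator

`generate_patient()` draws a `patient_profile` whose parameters are the
generative counterparts of the published 20-patient cohort summaries:

* per-axis dominant tremor frequency: normal, mean 5.5 Hz, SD 1.7 Hz,
  truncated to the physiological 2-12 Hz band (the truncation shifts the
  expectation slightly; `truncnorm_mean()` states the exact moment, and the
  generator tests check against that, not the nominal 5.5);
* per-axis baseline RMS angular velocity: log-normal with the reported
  per-axis mean/SD (13.19/19.46, 16.04/30.45, 8.25/12.80 in gyro units) —
  the reported cohort is strongly right-skewed, which a normal cannot
  represent with a positive support;
* response threshold: truncated normal, mean 9.45 mA, SD 4.29 mA, bounds
  3-17 mA (the observed range of maximum pulse amplitudes);
* suppression floor (fraction of tremor amplitude remaining under effective
  stimulation): uniform on (0.1, 0.4). The upper bound is kept below 0.5 so
  an effective stimulation always satisfies the >50% reduction criterion;
* reset hold: log-normal matched to the reported mean 129.55 s / SD
  226.71 s of post-withdrawal reduction, truncated to 5-480 s so that
  re-emergence is typically observable within a 10-minute post-stimulation
  section;
* re-emergence ramp: uniform 10-30 s, and additive noise SD uniform
  0.2-1.0 gyro units. Neither is reported anywhere; these are fixed
  once as plausible physiological scales (tens of seconds of gradual
  re-emergence; noise small relative to tremor RMS).

`simulate_session()` renders a session as a per-axis sinusoid at the
patient's frequency with amplitude `sqrt(2) * baseline_rms` times a
suppression envelope, plus Gaussian noise. The envelope is piecewise:
1 at baseline; slewing to the suppression floor over 0.5 s once the pulse
amplitude reaches the response threshold (a physiological smoothing that is
immaterial at the 1-s feature scale); held at the floor for `reset_hold`
seconds after withdrawal; then returning linearly to 1 over
`reemergence_ramp` seconds. The default protocol is the manual one: pulse
amplitude raised 1 mA about every 10 s until the threshold is reached, held
~30 s, then off. The sampling rate defaults to 50 Hz (not reported for the
device; all downstream windowing is rate-agnostic, requiring only >= 25 Hz
for the 12 Hz band). A simple sinusoid-plus-noise model is deliberate: the
cohort is characterized only by per-axis RMS and dominant frequency, both of
which this satisfies; the generator makes no claim about waveform shape,
within-session amplitude drift, harmonics, or voluntary-movement artefacts,
so passing tests demonstrate correctness of the *analysis machinery*, not
clinical performance on real recordings.

`reset_time_truth()` exposes the closed-form reset-time decomposition
implied by those dynamics (e.g. C = `reset_hold + ramp * (thr - floor) /
(1 - floor)` for a re-emergence threshold `thr`); the session metrics are
tested to land within ±2 s of it.

## Features and session metrics

`rms_windows()` aggregates the stream into non-overlapping half-open 1-s
windows anchored at session start (the window convention is a choice; only
"an interval of 1 s" is prescribed), computing per-axis RMS; the window's
pulse amplitude is the modal sample value with ties resolved to the later
value, matching a stepped protocol where changes within a second are rare.
`dominant_frequency()` is a zero-padded periodogram maximum over 2-12 Hz
with grid resolution <= 0.0625 Hz. No detrending is applied before the RMS
(a resting gyroscope is zero-mean); a `demean` flag exists for real logs.

Session metrics follow the protocol's three sections (before / during /
after, segmented from the windowed pulse amplitude). Baseline is the
per-axis **median** RMS over the before section (robust to movement
artefacts; at least 30 baseline windows are required). A window is
"reduced" when the 3-axis RMS magnitude falls below 50% of the baseline
magnitude; the state machine requires `persistence_k = 3` consecutive
windows to enter or leave the state, rejecting single-window noise at 1-s
resolution. The reduction criterion uses the 3-axis magnitude (the axis is
not prescribed), while the separate 2.5x stopping rule uses the x and y
axes only, exactly as specified clinically. Re-emergence "to the
pre-stimulation level" is operationalized as magnitude >= 75% of baseline
(no numeric threshold is prescribed; configurable). The reset summary is

* A: during-section length; B: reduced time within during;
* C: time from stimulation off to first re-emergence (0 when the tremor was
  not reduced at switch-off; censored and flagged when the session ends
  first);
* D = B + C. The additive definition is adopted because the reported cohort
  means satisfy it exactly (200.35 + 129.55 = 329.90 s), which excludes the
  pre-reduction ramp time from D.

A clinical-rating-based reduction criterion exists in the protocol but is a
human judgement; it is representable only as an externally supplied flag
and is never computed here.

## The labelled dataset

Pulse amplitude maps to five stimulation classes (0; 1-5; 6-10; 11-15;
>= 16 mA -> classes 0-4, non-integers floored first), with class maxima 0,
5, 10, 15, 20 mA. Each retained 1-s window becomes a record with features
RMS x/y/z and the *observed* previous window's class (`prev_class`,
teacher forcing; the first record of a patient is padded with 0 — the
protocol starts unstimulated). `filter_records()` drops during-section
windows where the tremor is present yet no amplitude is applied (manual
mid-exploration switch-offs — misleading training examples); the rule is
criteria-driven and every removal is logged. Folds are assigned
patient-wise (20 patients -> 7/7/6) so no patient leaks across the
train/test boundary; fold class percentages are always recomputed from
counts.

## The model suite

Five families predict the stimulation class from either the gyroscope RMS
alone or RMS plus `prev_class`: multinomial logistic regression
(`nnet::multinom`; the baseline, no grid — with at most four inputs there
is nothing to prune), random forest (`randomForest`, 100 trees, sqrt(p)
features per split, bootstrap), SVM (`e1071`, RBF, C = 1), a
two-hidden-layer (100, 100) perceptron, and a two-layer 100-unit LSTM with
a dense softmax head trained with Adam at learning rate 0.001. Feature
standardization is fitted on training data only and applied for SVM, the
perceptron and the LSTM; logistic regression and the forest use raw
features. The perceptron and the LSTM are implemented in this package with
BLAS matrix operations (gradient-checked in the test suite): no installed R
package offers a multi-hidden-layer perceptron or a recurrent network.

Grid search enumerates the documented ranges (forest: trees
{50..500} x bootstrap x split criterion x min leaf {2..30} = 120
candidates; SVM: C {0.5, 1, 2} x 4 kernels; perceptron: 6 layouts x
{tanh, relu} x {lbfgs, sgd, adam}) and selects by macro-F1 on an inner
2-fold patient-wise split of the training folds — the original procedure
does not describe its inner validation, and this is the cheapest scheme
that preserves grouping. One backend limitation: the installed forest
implementations provide only the Gini impurity, so candidates requesting
the entropy criterion are fitted with Gini (the requested value is
recorded); the grid's cardinality and enumeration are unaffected.

LSTM training details beyond the documented ones are defaults chosen once:
batches of 32 truncated-BPTT chunks of 60 windows with state reset per
chunk, 30 epochs. The network is uni-directional by construction — the
controller must act on past data only. Evaluation is teacher-forced
(observed `prev_class`), matching the stated limitation of the original
analysis; the closed-loop controller below is the free-running
counterpart. Macro metrics average precision/recall/F1 (0/0 := 0) over the
classes present in the true labels; a test fold with no records of a class
excludes that class from its macro mean (logged per fold) rather than
averaging in an undefined 0.

## The closed-loop controller

`controller_step()` closes the loop the original study left as future
work: each second the model receives the current RMS features and its own
previous *predicted* class (free-running), and the commanded amplitude
slews by at most 1 mA per step towards the predicted class's maximum.
When the 2.5x stopping rule fires (x- and y-RMS versus the reference
captured at stimulation onset), stimulation switches off immediately and
the controller stays stopped for the session — no re-arm policy is
defined clinically, so remaining stopped is the conservative default; a
configurable hold (`hold_s`, e.g. the manual protocol's ~30 s) can defer
the switch-off. With an oracle model and a noise-free patient the rule
fires exactly when the suppression floor is <= 0.4 = 1/2.5, which the
tests verify. `run_closed_loop()` simulates the whole loop against a
virtual patient and summarizes the resulting stream with the same session
metrics as a manual session.

## Supporting statistics

Before/during comparisons use the paired Wilcoxon signed-rank test (the
paired variant, following the clinical tables; zero differences dropped,
exact distribution for up to 25 untied pairs, tie-corrected normal
approximation otherwise). Correlations are Spearman's rho with midranks
and a t-approximate p-value. The reset-time regression is SPSS-style
stepwise OLS (entry p <= 0.05, removal p >= 0.10 — the defaults of the
tooling the original analysis used), with collinear candidates dropped
and warned about. `reference_reset_model()` carries the published fit
D = -98.336 + 48.559 E + 0.282 A; evaluated at the cohort means
(E = 6.25 mA, A = 440.7 s) it reproduces the mean reset time within the
rounding of the printed coefficients — the OLS through-the-means
identity, which the test suite also verifies exactly on freshly fitted
synthetic cohorts. A chi-square wrapper (optional Yates correction) is
included for categorical comparisons; no worked example anchors it.

## Numerical choices and problem sizes

Degenerate inputs are flagged, not thrown, where a session can genuinely
produce them: censored C, single-class training folds (constant
predictor), all-zero Wilcoxon differences, constant correlation inputs.
Division guards: RMS floored at machine epsilon in the stopping rule;
0/0 := 0 in precision/recall. Ties: modal window amplitude resolves to
the later value; grid-search ties to the earlier candidate.

The test suite and examples run at desk scale: cohorts of 6-20 virtual
patients, sessions of 5-15 simulated minutes, and a 20-patient x
600-window benchmark task for the learning-sanity checks, on which every
family with the `prev_class` feature exceeds 0.9 macro-F1 and every
ablation to gyroscope-only features degrades it — the direction, not the
magnitude, of the original finding is what synthetic data can establish.
All randomness fans out deterministically from explicit seeds;
reports embed the seed.

## Known limitations

* The generator's stationary single-tone tremor cannot exhibit real-world
  amplitude drift, harmonics, or voluntary movement; results on it bound
  implementation correctness only.
* The forest backend's Gini-only impurity collapses one grid axis (above).
* Free-running closed-loop behaviour of models trained with teacher
  forcing is exactly the deployment gap the original study flags; both
  modes are implemented so the gap can be measured, not hidden.
* The clinical headline scores (LSTM macro-F1 0.736, accuracy 0.865 on
  real recordings) are report-shape references, not reproduction targets:
  the recordings are unavailable.
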