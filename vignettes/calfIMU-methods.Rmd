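---
title: "Methods: collar-IMU behavior classification for pre-weaned calves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collar-IMU behavior classification for pre-weaned calves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In cow–calf contact rearing, a calf's feeding-related behaviors (natural
suckling at the dam, feeding at the trough, rumination), its posture
(lying, standing) and respiratory events (coughing) are all welfare- and
health-relevant, and they co-occur: a calf ruminates while lying, suckles
while standing. A single collar-mounted six-axis IMU — triaxial
accelerometer in g, triaxial gyroscope in deg/s, sampled at 25 Hz with
±4 g and ±500 deg/s full scales — can observe all of them, but no single
classifier handles both long continuous behaviors and sub-2-second events
well. calfIMU therefore implements three complementary models over one
signal representation:

* **Model 1** — four feeding-related action classes
  (`natural_suckling`, `rumination`, `feeding`, `others`) on 10 s windows;
* **Model 2** — two postural states (`lying`, `standing`) on the same
  windows;
* **Model 3** — `coughing` vs `non_coughing` on short event windows
  anchored at acceleration-magnitude peaks.

## Signal representation and windowing

Beyond the six raw axes, two orientation-robust magnitude channels are
derived per sample: the acceleration magnitude `am = sqrt(ax^2 + ay^2 +
az^2)` and the angular-velocity magnitude `gm` analogously. For Models 1–2
the series is cut into windows of 10 s with 50 % overlap — 250 samples per
window with a 125-sample stride at 25 Hz. Trailing partial windows are
dropped to preserve the fixed geometry. Indices are 0-based and half-open;
a window's timestamp is its start-sample time.

A window's **action label** is the action-tier behavior occupying
*strictly more than half* of its span, otherwise `others`; its **state
label** is the state-tier majority. Exactly-50 % action occupancy is not a
majority and yields `others`; an exact 50/50 state split resolves to the
earlier-starting state (logged). Both labels are always assigned —
actions and postures co-occur, so a window can legitimately be
(`rumination`, `lying`).

Coughs are too short and rare for exhaustive short windows. Instead,
local maxima of `am` above a threshold (default 1.3 g) with a minimum
spacing (default 1.0 s) are detected; spacing conflicts keep the larger
peak (ties to the earlier index). Each retained peak anchors a 31-sample
event window — the peak plus 15 samples on each side. Peaks within 15
samples of a boundary are dropped rather than padded, keeping the feature
geometry fixed. An event window is labelled `coughing` iff an annotated
cough interval intersects its time span.

The peak threshold and spacing are not dictated by any external
convention we could adopt, so they are configuration-exposed
(`peakConfig()`); the defaults detect the simulator's cough transients
while quiescent posture produces no peaks (baseline `am` is ≈1 g gravity
plus noise, 99.9th percentile ≈1.15 g).

At inference time the daily time-budget conversion assigns 10 s to each
predicted window, so prediction runs on *non-overlapping* windows
(overlap 0) to avoid double-counting; training keeps the 50 % overlap for
sample efficiency.

## Features

Every window yields a 12-statistic × 8-channel grid (96 features): mean,
variance, SD, min, max, IQR, zero crossings, dominant DFT frequency and
its power, and the mean, max and SD of the absolute forward-difference
gradient, per channel `ax, ay, az, gx, gy, gz, am, gm`. The families map
to behaviors as follows: static orientation and variance separate lying
from standing; the dominant frequency of the nodding-axis gyroscope
captures the periodic head motion of suckling; IQR and zero crossings
capture chewing oscillation in rumination and feeding; gradient
statistics capture the sharp transients of coughs.

Numerical conventions, chosen once where more than one convention exists:

* **Dominant frequency**: the series is mean-removed and the DC bin and
  upper half-spectrum excluded (periodicity is sought, and DC is not
  periodicity); the maximal-power bin among `1 ≤ k ≤ floor(N/2)` is
  reported as `k·fs/N`; an all-constant window reports `(0, 0)`. Ties take
  the lowest frequency.
* **IQR**: `Q3 − Q1` under the linear-interpolation ("type 7") quantile
  rule.
* **Zero crossings**: counted after mean-centering; exact zeros inherit
  the previous nonzero sign, so touching zero without reversal does not
  count.
* **Gradient**: forward differences `(x[n+1] − x[n])/Δt`, giving N−1
  values per N-sample window.

Feature selection runs in two stages, fitted on training rows only and
then applied to the whole table: (1) a greedy correlation filter in fixed
column order drops any feature whose absolute Pearson correlation with an
already-kept feature reaches 0.9 (constant columns are dropped outright;
a correlation against a zero-variance column is defined as 0); (2) a
single seeded classification tree ranks features by impurity importance
and features the tree never uses (exact-zero importance) are dropped.
Both stages emit reports that partition the original feature set, so the
selection funnel is auditable. The surviving counts are outcomes of the
data, not targets.

## Classifiers

All three models are gradient-boosted tree ensembles grown leaf-wise
(`tree_method = "hist"`, `grow_policy = "lossguide"`), trained
single-threaded with fixed seeds so that splits, training and prediction
are bit-reproducible. Train/test splitting is *individual-wise*: whole
calves are assigned to the test set (default 6 of 48), because windows
from one calf are strongly dependent and the deployment question is
generalisation to unseen animals. Within the training calves a row-level
8:2 train/validation split drives early stopping (50 rounds patience on
validation log-loss) and hyperparameter tuning. The 8:2 split is taken at
the row level; calf-level validation splitting would be the conservative
alternative, but with 42 training calves it leaves validation sets too
small and unbalanced at this cohort scale.

Cough events are rare, so Model 3's training rows are rebalanced with
SMOTE: synthetic minority rows are drawn on segments between a minority
row and one of its 5 nearest minority neighbours, with a uniform
interpolation factor, until the classes are 1:1. Originals are preserved;
validation and test rows are never oversampled, and stratified k-fold
cross-validation (default k = 5) applies SMOTE inside each training fold
only. Hyperparameter search (`tuneHyperparameters()`) is a seeded random
search over learning rate (log-uniform), number of estimators and max
depth, scored by validation macro F1, with the full trial log returned.

## Evaluation

Per-class metrics are one-vs-rest: accuracy, TPR (sensitivity), TNR
(specificity), PPV (precision) and F1 = 2·PPV·TPR/(PPV+TPR), reported in
percent. The **Overall** row is the unweighted macro average; metrics
with zero denominators are undefined (NA), logged, and excluded from the
macro rather than zero-filled. In binary models the TPR of one class is
the TNR of the other, and the two classes share one accuracy — a
structural identity the tests assert. ROC curves sweep all score
thresholds; AUC is trapezoid-integrated and equals the pairwise
concordance probability with ties counted ½ (asserted against an O(n²)
oracle and an established ROC package).

Daily validation converts predicted windows into time budgets (10 s per
window, per calf-day and behavior) and correlates them with annotated
durations via Pearson's r; coughs are validated as daily counts, not
seconds. Inter-observer agreement uses Cohen's kappa
`K = (P0 − Pc)/(1 − Pc)` on label sequences binned to a common 1 s
lattice — the bin width is a preprocessing choice, exposed as an
argument. Kappa is reported on its natural [−1, 1] scale.

## The synthetic cohort

No public recording of collar-IMU calf data with tiered annotations is
available, so the package ships a simulator that is itself first-class,
tested code. It emulates exactly the signal structure the feature
families are designed to detect:

* distinct gravity orientations with different noise floors for lying
  ((1,0,0), accel SD 0.02 g) vs standing ((0,0,1), accel SD 0.05 g);
* a 1.5 Hz nodding oscillation (80 deg/s) on the nodding-axis gyroscope
  during natural suckling;
* chewing oscillations at 1.2 Hz (rumination) and 2.2 Hz (feeding) on
  gyroscope x with a small accelerometer component;
* sharp biphasic ~0.4–0.8 s acceleration transients (1.5–2.6 g peak) for
  coughs, injected at Poisson times (default 6/h) with sub-2 s durations;
* smoother unlabelled "bump" transients (head knocks, ~1.0–1.6 s) at 2.8×
  the cough count, so that peak detection yields non-cough event windows
  at the 2.8:1 event-class imbalance that motivates the SMOTE stage.

Bout schedules alternate lying/standing with log-normal durations (median
15 min lying, ~12 min standing, truncated to 2–60 min) and interleave
action bouts (log-normal, median 2.5 min) with untagged gaps that the
labeling rule turns into `others` windows. All draws are seeded;
identical scenarios render bit-identical recordings.

What the simulator does **not** model: collar slippage, sensor drift or
temperature effects, dam motion transmitted through contact, individual
variation in oscillation frequency beyond bout-level phase, or the true
spectral content of calf behavior at 25 Hz — the signature frequencies
are plausible defaults, not measurements. Passing the recovery tests
therefore demonstrates that the pipeline's machinery (windowing,
labeling, features, leakage-safe training, evaluation) is correct and
that the three models can exploit exactly the intended signal families;
it does not certify field performance on real calves.

## Problem sizes and verification

The package's own end-to-end verification uses a 48-calf cohort at 2 h
per calf with a 42/6 individual-wise split — the cohort geometry of the
design, at a recording length chosen to keep a full run in the
single-digit minutes on one CPU. At that scale the suite requires
held-out-calf macro F1 ≥ 0.90 (Model 1), ≥ 0.95 (Model 2) and cough
F1 ≥ 0.75 (Model 3). Arithmetic identities of the metric layer (the F1
harmonic-mean identity and macro averaging) are checked against reference
per-class metric tables shipped under `inst/extdata/`, reproducing every
overall cell to two decimals. Fast numeric paths are verified against
naive oracles: the FFT-based dominant frequency against the O(N²) DFT
sum, trapezoid AUC against pairwise concordance, peak detection against
a brute-force spacing filter, and confusion counting against an
independent tally.

`scripts/acceptance.R` re-runs this verification from scratch against the
installed package and writes the measured quantities as JSON; see the
README for invocation.
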