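---
title: "Methods: physiological evaluation of audiovisual content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological evaluation of audiovisual content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

`physioad` implements an end-to-end analysis that rates short audiovisual
stimuli (TV commercials) as *positive*, *neutral* or *negative* in
effectiveness from the viewer's physiology. A viewing session is a ~30-min
documentary interrupted by three blocks of three ads; the two minutes of
documentary before each block serve as a neutral baseline. Four signals are
recorded concurrently: 30-channel EEG and single-lead ECG at 256 Hz, and
skin conductance (GSR) and respiration at 32 Hz. Per (subject, ad)
instance the package computes fixed feature batteries, assembles dataset
variants, balances and standardizes them, and runs a staged classifier
protocol whose final model labels a held-out, unrated ad.

Because no public recordings exist for this design, the package ships a
synthetic session generator whose outputs carry configurable
class-conditional structure; every stage of the pipeline is tested against
that generator's ground-truth ledger.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests and the acceptance script.

* **Timeline.** Documentary segments of 420, 345, 765 and 0 s interleaved
  with three ad blocks of three 30-s ads (1800 s total): the first block at
  minute 7, the second mid-session, the third at the end. Ad order is a
  seeded permutation *per subject*, mirroring the randomization that removes
  presentation order as a confound. (An early version shared one order
  across the cohort; under null effects the classifiers then scored well
  above chance purely from ad position, which is exactly the "sequence"
  confound the design exists to kill. Per-subject orders and random
  oscillator phases eliminate it; the null control verifies this.) Brand
  windows default to seconds 12-15 and 25-30 of each ad.
* **EEG.** Per channel: pink (1/f) background (10 µV), an alpha oscillator,
  and on the twelve frontal sites theta (6 Hz) and beta (20 Hz) oscillators
  whose gain is multiplied by the ad class's `frontal_band_gain` while an ad
  plays. Blinks are a Poisson process (0.25/s) of 400-ms raised-cosine
  deflections, 80 µV at Fp decaying to 15% at Fc. Optional flat and
  heavy-tailed-spike channels exercise the QC path.
* **ECG.** RR intervals are built beat by beat: a base interval (850 ms)
  times the class's `rr_mean` multiplier, plus LF (0.1 Hz) and HF (0.25 Hz)
  sinusoids with subject-random phases, a slow drift (30 ms amplitude,
  45-s period) scaled by `rr_drift`, and white noise (8 ms). A PQRST
  Gaussian-sum template is placed at the cumulative R times.
* **GSR.** A smooth tonic level (spline through sparse random knots plus a
  10-min sinusoid) plus bi-exponential sudomotor responses (rise 0.75 s,
  decay 3 s, ~0.35 µS) at a Poisson rate of 0.03/s during documentary and
  0.12/s times the class's `gsr_peak_rate` during ads.
* **RSP.** A frequency-modulated sinusoid around 0.25 Hz.

The strong-effects preset encodes raised sympathetic arousal for effective
ads (more sudomotor events, shorter RR, larger drift, higher frontal gain);
the null preset removes every class difference. The unlabeled holdout ad is
generated with positive-class physiology, so the protocol's holdout vote
has a known right answer. A missing-data model drops EEG for 12/47, ECG and
respiration for 4/47, and GSR for 3/47 of subjects.

What the generator does *not* emulate: volume-conducted source mixing and
realistic scalp topographies, cardiorespiratory coupling, motion artifacts,
electrode drift, or inter-subject differences beyond lognormal effect
multipliers (SD 0.08). Passing tests therefore demonstrate that the
pipeline recovers the structure this generator plants — not that it would
reach any particular accuracy on real recordings.

## Preprocessing

**EEG.** Per-channel mean subtraction and a zero-phase order-4 Butterworth
band-pass (0.5-40 Hz). Channel QC computes each channel's kurtosis (plain,
non-excess, `K = mu4/sigma^4`) and rejects a channel when it is a montage
outlier (|robust z| > 3) or flat — |first difference| below 1e-6 of the
channel IQR — for more than 10% of the recording. The outlier statistic is
the *median intra-epoch* kurtosis rather than the whole-trace value: blinks
are sparse, so they inflate whole-trace kurtosis on every frontal channel
(robust z beyond 100 on synthetic sessions) without making the channel
corrupt, and a QC keyed to the whole trace would interpolate away exactly
the channels the downstream ICA needs to isolate the blink. A genuinely
spiky or broken channel is abnormal in most epochs and keeps a high median.
Rejected channels are replaced by
inverse-distance-weighted averages of their four nearest good electrodes in
the schematic 10-20 layout. The recording is then cut into 1-s epochs and
an epoch is dropped when any channel's intra-epoch kurtosis has |robust z|
> 8 across epochs; the cutoff deliberately targets catastrophic epochs
only, because ordinary blink epochs must survive to the ICA stage (at a
cutoff of 5 the decomposition never saw the blinks it is meant to remove,
and clean recordings lost ~7% of epochs; at 8 clean loss is well under 5%).

Artifact components are found by a seeded deflation FastICA (tanh
contrast). Deflation fits one direction at a time; once a direction fails
to converge the remaining subspace is treated as Gaussian noise and
completed with an orthonormal basis, and such components are never flagged.
This matters on synthetic data, where only a few directions (the blink
above all) are strongly non-Gaussian and a symmetric update cannot settle.
Each genuine component is scored for blink-likeness — frontal share of
mixing-vector energy × temporal kurtosis × max/median epoch variance — and
log-scores are split by 1-D 2-means; the upper cluster is rejected only
when the gap exceeds twice the pooled within-cluster spread *and* the
component is spiky (kurtosis > 5) and frontal (> 0.4). These floors keep
clean recordings at zero rejections. Flagged components are zeroed before
back-projection. The full published artifact-classification scheme this
replaces also relies on a manual expert pass that no pipeline can
reproduce; the simplified score addresses its blink class only.

**ECG.** Mean subtraction; linear-phase FIR high-pass at 0.5 Hz (4096
taps — the narrow transition is what a 0.5-Hz cutoff at 256 Hz costs); a
narrow zero-phase 50-Hz notch (pole radius 0.99); FIR low-pass at 65 Hz,
the midpoint of the 60-70 Hz range a muscle-noise cutoff conventionally
uses. All stages are zero-phase in effect (delay-compensated), so R-peak
latencies are untouched.

**GSR/RSP.** Grayscale morphological opening-then-closing with flat
elements of 0.5 s (GSR) and 0.25 s (RSP) — shorter than the narrowest
physiological event each signal carries — removes ripple while preserving
peak locations. Extremum detection is a sign-change scan with plateau
midpoints and enforced min/max alternation; the feature extractors
additionally merge extremum pairs with prominence below a small floor
(0.02 µS for GSR, 0.1 a.u. for RSP), a numerical tie-break that stops
instrument-noise wiggles surviving the morphology from being counted as
sudomotor or breath events.

## Feature batteries

**EEG (18 + 72 + 8 = 98).** Global field power over the twelve frontal
electrodes is computed per band (delta 1-3, theta 4-7, alpha 8-12, beta
13-24, extended beta 25-40, gamma 25-100 Hz — gamma is retained for
completeness but carries no energy above the 40-Hz low-pass) as the root
mean-per-electrode sum of pairwise potential differences, algebraically
`sqrt(2 * sum((u - mean(u))^2))`. The Zscore index standardizes
stimulus-period GFP by the mean and SD of the 2-min pre-block baseline GFP.
Per instance: mean GFP, mean Zscore and log(mean Zscore) per band (18;
the log is missing when the mean Zscore is non-positive); Welch mean band
power (128-sample windows — half a second at 256 Hz — 50% overlap,
rectangular taper as the periodogram is defined) for each band × frontal
electrode (72); and the 8 index features: mean theta and alpha Zscore, the
interest index (share of supra-threshold Zscore peaks — maximal contiguous
excursions at Z ≥ 3, counted by apex — whose apex falls in a brand window)
on theta and beta, and total/brand peak counts in theta and extended beta.
Peaks are evaluated per subject so they yield per-instance features; the
memorization and pleasantness indexes (normalized GFP envelopes averaged
within remember/forget and like/dislike groups, right-minus-left frontal
asymmetry for pleasantness, cubic smoothing splines with GCV-chosen
smoothing) remain group-level curve outputs, since they require averaging
across subjects.

**HRV (56).** R peaks by Pan-Tompkins (5-15 Hz band-pass, derivative,
squaring, 150-ms integration, adaptive dual thresholds with search-back and
a 200-ms refractory; candidates restricted to maxima dominating their
200-ms neighbourhood so integration-hump ripple cannot pre-empt the true
peak). The tachogram drops intervals outside 300-2000 ms or deviating more
than 20% from the 5-beat running median — the deterministic stand-in for
the expert review the original workflow used. The battery is 11 time-domain
metrics, 14 spectral metrics by Welch on a 4-Hz cubic-spline resampling, the
same 14 by Lomb-Scargle on the raw intervals, the 14 Welch metrics averaged
over 30-s windows at 50% overlap (time-frequency), and SD1/SD2/sample
entropy — 56 values with fixed names. The composition follows the
convention of HRV analysis tools that report these four domains with both
spectral estimators; the published analysis names the domains, its named
metrics and the total of 56, but not the full list. `t_SDANN` uses 30-s
windows (a 5-min convention would exceed a 30-s ad outright); on a single
ad it still has only one window and is missing — it becomes informative on
longer segments, which is where its generator-knob monotonicity is tested.
ULF/VLF band metrics are retained as features although they are
physiologically meaningful only in long registrations. Missing metrics stay
missing; the vector never shrinks.

**GSR (10) and RSP (6).** The ten conductance statistics (mean, variance,
SD, counts of local maxima/minima, mean min-to-max rise, global max/min and
range, peaks per second) and six respiration statistics (rate from
inhalation maxima, mean level, longest/shortest max-to-max inter-breath
interval, deepest/shallowest excursion).

## Evaluation protocol

Variants assemble per-signal tables by inner join on (subject, ad), so a
subject missing a signal leaves every variant containing it: GSR 10, RSP 6,
HRV 56, EEG_GFP-ZSCORE 18, EEG_PSD 72, EEG_IND 8, EEG_ALL 98, GSR+HRV 66,
GSR+HRV+EEG_IND 74, GSR+HRV+EEG_ALL 164 features.

Labelled instances are SMOTE-balanced (synthetic points uniform on segments
to one of k = 5 same-class nearest neighbours) and then z-standardized,
*before* cross-validation — the order the original analysis states. This
leaks minority-class information across folds and will bias a
no-information table above chance; fidelity wins by default, and a
leak-free mode (`balance = "fold"` in `cross_validate()`) applies both
steps inside each training fold for when the question is whether any class
information exists at all. Missing entries are mean-imputed at
standardization (zero after scaling). Classifiers: random forests via
`ranger` with 100 trees, unlimited depth and all features eligible at every
split (as the protocol specifies); AdaBoost.M1 with 10 iterations using
weight-proportional resampling (the base forest takes no instance weights;
resampling is the standard equivalent); one-against-all multiclass; bagging
with 10 replicates; and a baseline battery (SVM, multilayer perceptron,
multinomial logistic, naive Bayes, CART decision tree, 1-nearest-neighbour,
Zero Rule, One Rule). Two Weka-specific baselines (Decision Table,
Hoeffding tree) have no standard R implementation; the CART tree stands in
under its own name.

Cross-validation is 10-fold stratified (class counts per fold within one
instance); per-class accuracy is class recall aggregated over folds and the
reported "average" is their arithmetic macro mean. On a balanced table the
Zero Rule baseline yields exactly (100, 0, 0) and 33.33%. An optional
`group` argument assigns whole subjects to folds: the eight instances of a
subject are statistically dependent, and instance-level folds let a forest
memorize subjects — on null data this produces systematically *below*-chance
recall, because a subject's held-out labels are anti-correlated with its
residual training mix. The protocol and recovery experiments keep the
instance-level folds of the original design; the no-information controls
(null effects, RSP-only) use subject-level folds, and their chance band is
assessed on per-subject correctness (cluster-aware t-interval) rather than
an instance-binomial band that assumes independence.

Wrapper attribute selection is greedy forward search scored by internal
5-fold CV of the base classifier itself, stopping when no addition improves
the score. For an `ASC` (attribute-selected classifier) cascade the search
runs once per dataset before the outer CV — consistent with the
protocol's table-level SMOTE order, and the per-fold alternative is
computationally prohibitive at 100-tree forests × 66 features.

The staged protocol: round 1 cross-validates each variant with RF,
MCC+BAG+RF and ASC+RF; variants whose best average reaches 75% win. Round 2
evaluates GSR+HRV (plus GSR+HRV+EEG_IND / +EEG_ALL when those EEG variants
won). Round 3 re-evaluates GSR and the combinations under wrapper-selected
attributes with the extended cascade set (adding AB+RF and MCC+AB+RF). The
best round-3 cell is refit on its full table and applied to the unlabeled
ad; the cohort-level majority vote (ties broken alphabetically) is the
verdict.

## Problem sizes and numerical choices

The test suite and acceptance script use: a 930-s session (the shortest
layout the 7-min lead-in and 2-min baselines allow) for single-subject
signal tests; a 40-subject cohort at the full 1800-s session with the
strong preset and the default missing-data model for the recovery
experiment and protocol run (autonomic signals; the EEG feature paths are
exercised on small cohorts, where their dimensionalities are checked); and
a 24-subject null cohort. ICA fits on at most 50 000 samples (ample for 30
components); cleaning uses every sample. Spectral bins: EEG Welch windows
are fixed at 128 samples; tachogram Welch uses up to 1024 points of the
4-Hz resampling, so the VLF band (0.033-0.04 Hz) is resolvable on
session-length segments but empty (missing) on 30-s ads.

Known limitations: accuracies on synthetic cohorts say nothing quantitative
about real recordings (the published per-class tables are not reproducible
without the original data); the blink score addresses blinks only, not
saccades or muscle artifacts; Lomb-Scargle band powers are on the
estimator's own scale and are compared within, never across, estimators;
EDF export is not provided (CSV + JSON only).
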