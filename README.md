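# physioad

Automatic emotional evaluation of audiovisual content — TV commercials
rated **positive / neutral / negative** — from multimodal physiological
recordings: 30-channel EEG, single-lead ECG, galvanic skin response (GSR)
and respiration. The package is aimed at affective-computing and
neuromarketing researchers who need a tested, reproducible implementation
of this analysis without access to proprietary recordings: it ships a
synthetic session generator with class-conditional structure, so every
stage runs and is validated end to end.

## What it computes

A viewing session is a ~30-min documentary with three blocks of three
30-s ads; the 2 min of documentary before each block is the neutral
baseline. Per (subject, ad) instance:

* **EEG** — frontal Global Field Power per band,
  `GFP(t) = sqrt( Σᵢ Σⱼ (uᵢ(t) − uⱼ(t))² / Nₑ )`, standardized against the
  baseline as `Z(t) = (GFP(t) − mean(GFP_B)) / sd(GFP_B)`; supra-threshold
  peak counts (Z ≥ 3) and the interest index `II = PN_brand / PN_total`;
  Welch band power (128-sample windows, 50% overlap) for 6 bands × 12
  frontal electrodes. Feature sets of 18, 72, 8 and 98 values.
  Preprocessing: 0.5–40 Hz zero-phase band-pass, kurtosis/flatness channel
  QC (`K = μ₄/σ⁴`) with neighbour interpolation, 1-s epoch rejection, and
  seeded ICA blink-component removal.
* **HRV (56 metrics)** — Pan-Tompkins R-peak detection, tachogram with a
  deterministic artifact rule, then time-domain (maxRR … pRR50, SDANN,
  heart rate), frequency-domain (ULF/VLF/LF/HF powers, peaks, normalized
  and percentage powers, LF/HF) by both Welch and Lomb-Scargle,
  time-frequency (windowed Welch averages), and nonlinear
  (Poincaré SD1/SD2, sample entropy).
* **GSR (10)** and **respiration (6)** — morphologically smoothed traces:
  sudomotor peak counts and rises, conductance statistics, breath rate and
  inter-breath intervals.

The evaluation layer assembles dataset variants (GSR 10, RSP 6, HRV 56,
EEG variants 18/72/8/98, combinations 66/74/164 features), balances with
SMOTE, standardizes, and runs a three-round protocol of classifier
cascades — random forests under multiclass one-vs-all, AdaBoost.M1 and
bagging meta-schemes, with wrapper (forward, classifier-scored) attribute
selection — under 10-fold stratified cross-validation, reporting per-class
and macro ("average") accuracies, then votes on the held-out unrated ad.

## Worked example

Simulate a small cohort with strong class effects (autonomic signals
only), evaluate the GSR+HRV variant, and classify the unrated ad:

```r
library(physioad)

feats <- simulate_study(8, class_effects_strong(), seed = 42,
                        signals = c("ecg", "gsr", "rsp"),
                        drop_model = NULL,
                        config = session_config(doc_lengths = c(420, 120, 120, 0)))

tab      <- assemble_variant("GSR+HRV", feats)   # 66 feature columns
parts    <- split_holdout(tab)                   # 1 unlabeled ad x 8 subjects
prepared <- parts$labeled |>
  smote_balance(seed = 42) |>
  standardize_features()

cv <- cross_validate(prepared, classifier_spec("MCC+AB+RF", seed = 42),
                     k = 10, seed = 42)
cv
#> <cv_result> MCC+AB+RF on GSR+HRV: average 97.92%
#> # A tibble: 3 × 2
#>   class    accuracy
#>   <chr>       <dbl>
#> 1 negative    100
#> 2 neutral      93.8
#> 3 positive    100
```

Per-class numbers are class recalls over the folds (percent); the average
is their macro mean. The unrated ad is generated with positive-class
physiology, and the fitted cascade votes accordingly:

```r
model <- fit_cascade(classifier_spec("MCC+AB+RF", seed = 42), prepared)
hold  <- apply_standardization(parts$holdout, prepared)
predict_holdout(model, hold)$shares
#> negative  neutral positive
#>        0        0        1
```

`run_protocol(feats, seed = 42)` runs the full three-round staged
evaluation (round 1 per variant, 75% winner threshold, combinations,
wrapper-selected round 3) and returns a report with `tidy()`, `glance()`
and `autoplot()` methods. The EEG feature paths work the same way from
`generate_cohort()` / `extract_cohort_features()` bundles that include the
`"eeg"` signal.

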