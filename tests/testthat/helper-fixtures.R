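# Shared fixtures, built once per test run and cached. Sessions use the
# shortest documentary layout the design allows (7-min lead-in, 2-min
# baselines) to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

small_config <- function() {
  session_config(doc_lengths = c(420, 120, 120, 0))
}

small_timeline <- function() {
  cached("timeline", generate_timeline(small_config(), seed = 2))
}

# One subject's autonomic signals (ECG / GSR / RSP) with ground-truth ledger.
autonomic_bundle <- function() {
  cached("autonomic", {
    tl <- small_timeline()
    generate_subject(tl, subject_profile("s01", tl, rng_seed = 11),
                     signals = c("ecg", "gsr", "rsp"))
  })
}

# One subject's EEG with blinks, and its preprocessed form.
eeg_bundle <- function() {
  cached("eeg", {
    tl <- small_timeline()
    generate_subject(tl, subject_profile("s01", tl, rng_seed = 21),
                     signals = "eeg")
  })
}

eeg_preprocessed <- function() {
  cached("eeg_pp", preprocess_eeg(eeg_bundle()$eeg, 256, ica = TRUE,
                                  seed = 5))
}

# Small autonomic cohort feature set for evaluation-layer tests.
autonomic_features <- function() {
  cached("auto_feats", {
    suppressWarnings(simulate_study(
      8, class_effects_strong(), seed = 7,
      signals = c("ecg", "gsr", "rsp"), drop_model = NULL))
  })
}

# Clean ECG built directly from the PQRST template at a fixed heart rate.
template_ecg <- function(bpm, duration_s = 120, fs = 256, noise_sd = 0.01,
                         seed = 1) {
  rr_s <- 60 / bpm
  r_times <- seq(1, duration_s - 1, by = rr_s)
  n <- duration_s * fs
  x <- numeric(n)
  half <- round(0.35 * fs)
  offs <- (-half:half) / fs
  tmpl <- physioad:::pqrst_template(offs)
  for (rt in r_times) {
    idx <- round(rt * fs) + (-half:half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
  }
  withr::with_seed(seed, x + stats::rnorm(n, 0, noise_sd))
}

# A separable three-class feature table for classifier tests.
toy_feature_table <- function(n_per_class = 20, p_noise = 3, sep = 4,
                              seed = 1) {
  withr::with_seed(seed, {
    classes <- c("negative", "neutral", "positive")
    rows <- lapply(seq_along(classes), function(i) {
      tibble::tibble(
        subject = sprintf("s%02d", seq_len(n_per_class)),
        ad = sprintf("ad_%s_%d", classes[i], seq_len(n_per_class)),
        label = classes[i],
        signal = stats::rnorm(n_per_class, mean = i * sep),
        !!!stats::setNames(
          lapply(seq_len(p_noise), function(j) stats::rnorm(n_per_class)),
          paste0("noise", seq_len(p_noise)))
      )
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("feature_table", class(out))
    out
  })
}

# Study-scale fixtures for the acceptance suite: a 40-subject cohort with
# strong class effects (autonomic signals) and a 24-subject null cohort.
acceptance_features <- function() {
  cached("accept_feats", suppressWarnings(simulate_study(
    40, class_effects_strong(), seed = 11,
    signals = c("ecg", "gsr", "rsp"), drop_model = default_drop_model())))
}

null_features <- function() {
  cached("null_feats", suppressWarnings(simulate_study(
    24, class_effects_null(), seed = 21,
    signals = c("ecg", "gsr", "rsp"), drop_model = NULL)))
}

# Tiny full-signal cohort (EEG included) for dimensionality checks.
multimodal_features <- function() {
  cached("mm_feats", {
    co <- generate_cohort(2, class_effects_strong(), seed = 31,
                          config = small_config(), drop_model = NULL)
    extract_cohort_features(co, ica = FALSE)
  })
}
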