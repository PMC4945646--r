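#' Class-conditional effect multipliers
#'
#' Each ad class (positive / neutral / negative) scales four generator
#' parameters while that ad is on screen: the Poisson rate of skin
#' conductance responses (`gsr_peak_rate`), the mean RR interval
#' (`rr_mean`), the amplitude of the slow RR drift (`rr_drift`) and the
#' frontal theta/beta oscillator gain (`frontal_band_gain`). A multiplier of
#' 1 means "no different from documentary viewing". The unlabeled holdout ad
#' is generated with the positive-class multipliers, mirroring a campaign ad
#' expected to score well.
#'
#' `class_effects_strong()` encodes clearly separable autonomic responses
#' (sympathetic arousal raised for effective ads: more sweating events,
#' shorter RR, larger drift); `class_effects_null()` removes every
#' class-conditional difference and is the negative control.
#'
#' @return Tibble with columns `class`, `gsr_peak_rate`, `rr_mean`,
#'   `rr_drift`, `frontal_band_gain`.
#' @export
class_effects_strong <- function() {
  tibble::tibble(
    class = c("positive", "neutral", "negative", "unlabeled"),
    gsr_peak_rate = c(2.2, 1.0, 0.45, 2.2),
    rr_mean = c(0.90, 1.0, 1.10, 0.90),
    rr_drift = c(2.5, 1.0, 0.35, 2.5),
    frontal_band_gain = c(1.6, 1.0, 0.7, 1.6)
  )
}

#' @rdname class_effects_strong
#' @export
class_effects_null <- function() {
  tibble::tibble(
    class = c("positive", "neutral", "negative", "unlabeled"),
    gsr_peak_rate = 1, rr_mean = 1, rr_drift = 1, frontal_band_gain = 1
  )
}

#' Default ad labelling
#'
#' Nine ads: four positive, two neutral, two negative and one unlabeled
#' holdout (the ad under evaluation), the grouping shape of an Ace-Score
#' panel rating.
#'
#' @param ad_ids Ad identifiers, at least 9 when `design = "default"`.
#' @return Named character vector mapping ad_id to class.
#' @export
default_ad_labels <- function(ad_ids = sprintf("ad%02d", 1:9)) {
  assert_that(length(ad_ids) == 9, "default labelling expects 9 ads")
  stats::setNames(
    c(rep("positive", 4), rep("neutral", 2), rep("negative", 2), "unlabeled"),
    ad_ids
  )
}

#' Subject profile
#'
#' Per-subject generation parameters: seeds, per-ad remember/like flags and
#' the class-conditional effect multipliers (with subject-level lognormal
#' heterogeneity already applied).
#'
#' @param subject_id Identifier.
#' @param timeline A `session_timeline`.
#' @param ad_labels Named map ad_id -> class.
#' @param class_effects Effect tibble, see [class_effects_strong()].
#' @param rng_seed Integer seed for this subject's signals.
#' @param subject_sd Log-scale SD of subject-level multiplier heterogeneity.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, timeline,
                            ad_labels = default_ad_labels(),
                            class_effects = class_effects_strong(),
                            rng_seed = 1L, subject_sd = 0.08) {
  ads <- ad_blocks(timeline)
  assert_that(all(ads$ad_id %in% names(ad_labels)),
              "every ad in the timeline needs a label")
  eff <- class_effects
  flags <- with_local_seed(rng_seed + 1L, {
    cls <- unname(ad_labels[ads$ad_id])
    p_rem <- c(positive = 0.8, neutral = 0.55, negative = 0.35,
               unlabeled = 0.8)[cls]
    p_like <- c(positive = 0.75, neutral = 0.5, negative = 0.25,
                unlabeled = 0.75)[cls]
    tibble::tibble(
      ad_id = ads$ad_id, class = cls,
      remember = stats::runif(nrow(ads)) < p_rem,
      like = stats::runif(nrow(ads)) < p_like
    )
  })
  het <- with_local_seed(rng_seed + 2L, {
    m <- exp(stats::rnorm(4, 0, subject_sd))
    eff$gsr_peak_rate <- eff$gsr_peak_rate * m[1]
    eff$rr_mean <- eff$rr_mean * m[2]
    eff$rr_drift <- eff$rr_drift * m[3]
    eff$frontal_band_gain <- eff$frontal_band_gain * m[4]
    eff
  })
  structure(
    list(subject_id = subject_id, flags = flags, effects = het,
         ad_labels = ad_labels, rng_seed = as.integer(rng_seed)),
    class = "subject_profile"
  )
}

# Per-sample multiplier trace for one effect column: 1 during documentary,
# the class multiplier while an ad of that class is on screen.
effect_trace <- function(timeline, profile, column, times) {
  out <- rep(1, length(times))
  ads <- ad_blocks(timeline)
  eff <- profile$effects
  for (i in seq_len(nrow(ads))) {
    cls <- profile$ad_labels[[ads$ad_id[i]]]
    m <- eff[[column]][match(cls, eff$class)]
    sel <- times >= ads$onset[i] & times < ads$onset[i] + ads$duration[i]
    out[sel] <- m
  }
  out
}

# ---------------------------------------------------------------------------
# ECG

# RR-interval ground truth: base rhythm + LF (0.1 Hz) and HF (0.25 Hz)
# sinusoidal modulation + slow drift + white noise, with class multipliers
# applied to the base interval and the drift amplitude during ads.
simulate_rr_series <- function(timeline, profile, base_rr = 850,
                               lf_amp = 25, hf_amp = 15, drift_amp = 30,
                               drift_period = 45, noise_sd = 8, seed = 1L) {
  dur <- timeline$total_duration
  with_local_seed(seed, {
    n_max <- ceiling(dur / 0.3) # generous upper bound on beat count
    phase <- stats::runif(1, 0, 2 * pi)
    ph_lf <- stats::runif(1, 0, 2 * pi)
    ph_hf <- stats::runif(1, 0, 2 * pi)
    rr <- numeric(n_max)
    tt <- numeric(n_max)
    t <- 0
    k <- 0L
    noise <- stats::rnorm(n_max, 0, noise_sd)
    while (t < dur && k < n_max) {
      k <- k + 1L
      m_base <- effect_trace(timeline, profile, "rr_mean", t)
      m_drift <- effect_trace(timeline, profile, "rr_drift", t)
      rr_k <- base_rr * m_base +
        lf_amp * sin(2 * pi * 0.1 * t + ph_lf) +
        hf_amp * sin(2 * pi * 0.25 * t + ph_hf) +
        drift_amp * m_drift * sin(2 * pi * t / drift_period + phase) +
        noise[k]
      rr_k <- max(rr_k, 300)
      rr[k] <- rr_k
      t <- t + rr_k / 1000
      tt[k] <- t
    }
    keep <- seq_len(k)[tt[seq_len(k)] <= dur]
    list(rr_ms = rr[keep], r_times = tt[keep])
  })
}

# PQRST template evaluated at offsets (s) relative to the R apex.
pqrst_template <- function(offsets) {
  g <- function(mu, amp, sd) amp * exp(-((offsets - mu)^2) / (2 * sd^2))
  g(-0.2, 0.12, 0.025) + g(-0.035, -0.15, 0.012) + g(0, 1, 0.011) +
    g(0.04, -0.25, 0.014) + g(0.25, 0.35, 0.06)
}

simulate_ecg <- function(timeline, profile, fs = 256, seed = 1L,
                         noise_sd = 0.02, powerline = 0, baseline_wander = 0,
                         ...) {
  rrsim <- simulate_rr_series(timeline, profile, seed = seed, ...)
  n <- round(timeline$total_duration * fs)
  x <- numeric(n)
  half <- round(0.35 * fs)
  offs <- (-half:half) / fs
  tmpl <- pqrst_template(offs)
  for (rt in rrsim$r_times) {
    c0 <- round(rt * fs)
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
  }
  with_local_seed(seed + 7L, {
    x <- x + stats::rnorm(n, 0, noise_sd)
    tt <- seq_len(n) / fs
    if (powerline > 0) {
      x <- x + powerline * sin(2 * pi * 50 * tt)
    }
    if (baseline_wander > 0) {
      x <- x + baseline_wander * sin(2 * pi * 0.15 * tt +
                                     stats::runif(1, 0, 2 * pi))
    }
    list(ecg = x, r_times = rrsim$r_times, rr_ms = rrsim$rr_ms)
  })
}

# ---------------------------------------------------------------------------
# GSR

# Bi-exponential sudomotor response shape, unit peak amplitude.
scr_shape <- function(t, tau_rise = 0.75, tau_decay = 3) {
  s <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  s / max(s)
}

simulate_gsr <- function(timeline, profile, fs = 32, seed = 1L,
                         tonic_level = 2, base_rate_doc = 0.03,
                         base_rate_ad = 0.12, amp_mean = 0.35,
                         noise_sd = 0.005) {
  dur <- timeline$total_duration
  n <- round(dur * fs)
  tt <- seq_len(n) / fs
  with_local_seed(seed, {
    # tonic drift: smooth spline through sparse random knots (one per
    # ~2 min) plus a gentle sinusoid; slow enough not to spawn spurious
    # local maxima at the sudomotor-event time scale
    n_knots <- max(4L, ceiling(dur / 120))
    knot_t <- seq(0, dur, length.out = n_knots)
    knot_v <- cumsum(stats::rnorm(n_knots, 0, 0.08))
    tonic <- tonic_level + stats::spline(knot_t, knot_v, xout = tt)$y +
      0.15 * sin(2 * pi * tt / 600 + stats::runif(1, 0, 2 * pi))
    # event rate per sample: documentary base vs class-scaled ad rate
    mult <- effect_trace(timeline, profile, "gsr_peak_rate", tt)
    in_ad <- mult != 1 | {
      ads <- ad_blocks(timeline)
      Reduce(`|`, lapply(seq_len(nrow(ads)), function(i) {
        tt >= ads$onset[i] & tt < ads$onset[i] + ads$duration[i]
      }))
    }
    rate <- ifelse(in_ad, base_rate_ad * mult, base_rate_doc)
    events <- which(stats::runif(n) < rate / fs)
    # enforce a minimal 1.5-s spacing so responses stay resolvable
    if (length(events) > 1) {
      keep <- c(TRUE, diff(events) > 1.5 * fs)
      events <- events[keep]
    }
    x <- tonic
    shape_t <- seq(0, 10, by = 1 / fs)
    shp <- scr_shape(shape_t)
    amps <- amp_mean * exp(stats::rnorm(length(events), 0, 0.25))
    for (j in seq_along(events)) {
      idx <- events[j]:min(n, events[j] + length(shp) - 1L)
      x[idx] <- x[idx] + amps[j] * shp[seq_along(idx)]
    }
    x <- x + stats::rnorm(n, 0, noise_sd)
    list(gsr = x, scr_times = events / fs)
  })
}

# ---------------------------------------------------------------------------
# Respiration

simulate_rsp <- function(timeline, profile, fs = 32, seed = 1L,
                         base_freq = 0.25, freq_mod = 0.03, noise_sd = 0.03) {
  n <- round(timeline$total_duration * fs)
  with_local_seed(seed, {
    tt <- seq_len(n) / fs
    f <- base_freq + freq_mod * sin(2 * pi * tt / 120 +
                                    stats::runif(1, 0, 2 * pi))
    phase <- 2 * pi * cumsum(f) / fs
    x <- sin(phase) + stats::rnorm(n, 0, noise_sd)
    list(rsp = x, breath_freq = f)
  })
}

# ---------------------------------------------------------------------------
# EEG

# Band-limited oscillator: sinusoid with slowly drifting phase and amplitude.
eeg_oscillator <- function(n, fs, freq, amp) {
  phase_noise <- cumsum(stats::rnorm(n, 0, 0.15))
  amp_mod <- 1 + 0.3 * sin(2 * pi * seq_len(n) / (fs * 7) +
                           stats::runif(1, 0, 2 * pi))
  amp * amp_mod * sin(2 * pi * freq * seq_len(n) / fs + phase_noise)
}

# Pink (1/f) noise via FFT spectral shaping.
pink_noise <- function(n, sd = 1) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# 400-ms raised-cosine blink deflection.
blink_template <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  (1 - cos(2 * pi * t / 0.4)) / 2
}

simulate_eeg <- function(timeline, profile, fs = 256, seed = 1L,
                         background_sd = 10, blink_rate = 0.25,
                         blink_amp = 80, n_flat_channels = 0,
                         n_spike_channels = 0) {
  n <- round(timeline$total_duration * fs)
  pos <- electrode_positions()
  chans <- pos$channel
  nch <- length(chans)
  with_local_seed(seed, {
    tt <- seq_len(n) / fs
    gain <- effect_trace(timeline, profile, "frontal_band_gain", tt)
    eeg <- matrix(0, nch, n, dimnames = list(chans, NULL))
    for (c in seq_len(nch)) {
      x <- pink_noise(n, background_sd)
      x <- x + eeg_oscillator(n, fs, 10, 4) # posterior-dominant alpha
      if (pos$frontal[c]) {
        x <- x + gain * eeg_oscillator(n, fs, 6, 5)   # frontal theta
        x <- x + gain * eeg_oscillator(n, fs, 20, 2)  # frontal beta
      }
      eeg[c, ] <- x
    }
    # Poisson blinks on frontal rows, amplitude decaying Fp -> F -> Fc
    blink_gain <- stats::setNames(rep(0, nch), chans)
    blink_gain[c("Fp1", "Fpz", "Fp2")] <- 1
    blink_gain[c("F7", "F3", "Fz", "F4", "F8")] <- 0.45
    blink_gain[c("Fc5", "Fc1", "Fc2", "Fc6")] <- 0.15
    tmpl <- blink_template(fs)
    n_blinks <- stats::rpois(1, blink_rate * timeline$total_duration)
    blink_times <- sort(stats::runif(n_blinks, 1, timeline$total_duration - 1))
    if (length(blink_times) > 1) {
      blink_times <- blink_times[c(TRUE, diff(blink_times) > 0.6)]
    }
    for (bt in blink_times) {
      idx <- round(bt * fs) + seq_along(tmpl) - 1L
      idx <- idx[idx >= 1 & idx <= n]
      eeg[, idx] <- eeg[, idx] +
        blink_amp * outer(blink_gain, tmpl[seq_along(idx)])
    }
    corrupt <- list(flat = character(), spiky = character())
    non_frontal <- chans[!pos$frontal]
    if (n_flat_channels > 0) {
      corrupt$flat <- sample(non_frontal, n_flat_channels)
      for (ch in corrupt$flat) {
        run <- round(0.15 * n)
        start <- sample.int(n - run, 1)
        eeg[ch, start:(start + run - 1L)] <- eeg[ch, start]
      }
    }
    if (n_spike_channels > 0) {
      corrupt$spiky <- sample(setdiff(non_frontal, corrupt$flat),
                              n_spike_channels)
      for (ch in corrupt$spiky) {
        at <- sample.int(n, max(5, round(n / fs / 4)))
        eeg[ch, at] <- eeg[ch, at] + stats::rt(length(at), df = 1.5) * 80
      }
    }
    list(eeg = eeg, blink_times = blink_times, corrupt = corrupt)
  })
}

# ---------------------------------------------------------------------------
# Bundles and cohorts

#' Generate one subject's signal bundle
#'
#' Synthesizes synchronized EEG (30 channels, 256 Hz), single-lead ECG
#' (256 Hz), skin conductance (32 Hz) and respiration (32 Hz) over a session
#' timeline, with class-conditional structure taken from the subject profile.
#' A ground-truth `ledger` (R-wave times, RR intervals, blink times, skin
#' conductance response times) is attached for validation.
#'
#' @param timeline A `session_timeline`.
#' @param profile A [subject_profile()].
#' @param signals Which traces to synthesize; EEG is by far the most
#'   expensive and may be dropped when only autonomic features are needed.
#' @param eeg_args,ecg_args,gsr_args,rsp_args Optional lists of overrides
#'   passed to the per-signal simulators (noise levels, artifact counts,
#'   powerline interference, ...).
#' @return A `signal_bundle`: matrices/vectors per signal, sampling rates,
#'   the timeline, the profile, and the ground-truth ledger.
#' @export
generate_subject <- function(timeline, profile,
                             signals = c("eeg", "ecg", "gsr", "rsp"),
                             eeg_args = list(), ecg_args = list(),
                             gsr_args = list(), rsp_args = list()) {
  seeds <- derive_seeds(profile$rng_seed, 4)
  out <- list(eeg = NULL, eeg_channels = NULL, ecg = NULL, gsr = NULL,
              rsp = NULL,
              fs = list(eeg = 256, ecg = 256, gsr = 32, rsp = 32),
              timeline = timeline, profile = profile,
              ledger = list())
  if ("eeg" %in% signals) {
    e <- do.call(simulate_eeg,
                 c(list(timeline, profile, fs = 256, seed = seeds[1]),
                   eeg_args))
    out$eeg <- e$eeg
    out$eeg_channels <- rownames(e$eeg)
    out$ledger$blink_times <- e$blink_times
    out$ledger$corrupt_channels <- e$corrupt
  }
  if ("ecg" %in% signals) {
    e <- do.call(simulate_ecg,
                 c(list(timeline, profile, fs = 256, seed = seeds[2]),
                   ecg_args))
    out$ecg <- e$ecg
    out$ledger$r_times <- e$r_times
    out$ledger$rr_ms <- e$rr_ms
  }
  if ("gsr" %in% signals) {
    e <- do.call(simulate_gsr,
                 c(list(timeline, profile, fs = 32, seed = seeds[3]),
                   gsr_args))
    out$gsr <- e$gsr
    out$ledger$scr_times <- e$scr_times
  }
  if ("rsp" %in% signals) {
    e <- do.call(simulate_rsp,
                 c(list(timeline, profile, fs = 32, seed = seeds[4]),
                   rsp_args))
    out$rsp <- e$rsp
  }
  structure(out, class = "signal_bundle")
}

#' @export
print.signal_bundle <- function(x, ...) {
  have <- names(Filter(Negate(is.null), x[c("eeg", "ecg", "gsr", "rsp")]))
  cat(sprintf("<signal_bundle> subject %s, %.0f s, signals: %s\n",
              x$profile$subject_id, x$timeline$total_duration,
              paste(have, collapse = ", ")))
  invisible(x)
}

#' Default missing-data model
#'
#' Fractions of subjects whose EEG, ECG+respiration, or GSR recordings are
#' dropped as corrupted, matching a realistic attrition pattern (12, 4 and 3
#' of 47 subjects respectively). ECG and respiration are dropped together
#' (both ride on the same amplifier inputs).
#'
#' @return Named numeric vector of drop fractions.
#' @export
default_drop_model <- function() {
  c(eeg = 12 / 47, ecg_rsp = 4 / 47, gsr = 3 / 47)
}

#' Generate a cohort of subjects
#'
#' Draws per-subject profiles with independent sub-seeds, synthesizes their
#' signal bundles and applies the missing-data model. Each subject receives
#' their own seeded ad-order permutation of the shared block structure, so
#' presentation order cannot masquerade as a class effect downstream.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param class_effects Effect tibble ([class_effects_strong()] by default).
#' @param seed Master seed.
#' @param config Session design ([session_config()]).
#' @param signals Signals to synthesize before the drop model is applied.
#' @param drop_model Named drop fractions as in [default_drop_model()]; use
#'   `NULL` to keep every signal for every subject.
#' @param ad_labels Named map ad_id -> class.
#' @param ... Passed on to [generate_subject()].
#' @return A `cohort`: list with `subjects` (list of signal bundles, each
#'   carrying its own timeline), `ad_labels`, `timeline` (the block layout
#'   with the cohort-seed ad order, for reference).
#' @export
generate_cohort <- function(n_subjects, class_effects = class_effects_strong(),
                            seed = 1L, config = session_config(),
                            signals = c("eeg", "ecg", "gsr", "rsp"),
                            drop_model = default_drop_model(),
                            ad_labels = default_ad_labels(config$ad_ids),
                            ...) {
  assert_that(n_subjects >= 1, "need at least one subject")
  seeds <- derive_seeds(seed + 1L, n_subjects)
  dropped <- cohort_drops(n_subjects, drop_model, seed)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    timeline <- generate_timeline(config, seed = seeds[i])
    profile <- subject_profile(sprintf("s%02d", i), timeline,
                               ad_labels = ad_labels,
                               class_effects = class_effects,
                               rng_seed = seeds[i])
    keep <- setdiff(signals, dropped[[i]])
    generate_subject(timeline, profile, signals = keep, ...)
  })
  structure(list(subjects = subjects, ad_labels = ad_labels,
                 timeline = generate_timeline(config, seed = seed),
                 seed = seed),
            class = "cohort")
}

# Which signals are dropped for each subject under the missing-data model.
cohort_drops <- function(n_subjects, drop_model, seed) {
  out <- replicate(n_subjects, character(), simplify = FALSE)
  if (is.null(drop_model)) return(out)
  with_local_seed(seed + 2L, {
    n_eeg <- round(drop_model[["eeg"]] * n_subjects)
    n_ecg <- round(drop_model[["ecg_rsp"]] * n_subjects)
    n_gsr <- round(drop_model[["gsr"]] * n_subjects)
    for (i in sample.int(n_subjects, min(n_eeg, n_subjects))) {
      out[[i]] <- c(out[[i]], "eeg")
    }
    for (i in sample.int(n_subjects, min(n_ecg, n_subjects))) {
      out[[i]] <- c(out[[i]], "ecg", "rsp")
    }
    for (i in sample.int(n_subjects, min(n_gsr, n_subjects))) {
      out[[i]] <- c(out[[i]], "gsr")
    }
    out
  })
}

#' @export
print.cohort <- function(x, ...) {
  has <- function(sig) {
    sum(vapply(x$subjects, function(s) !is.null(s[[sig]]), logical(1)))
  }
  cat(sprintf(
    "<cohort> %d subjects (eeg %d, ecg %d, gsr %d, rsp %d), %d ads\n",
    length(x$subjects), has("eeg"), has("ecg"), has("gsr"), has("rsp"),
    length(x$ad_labels)))
  invisible(x)
}
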