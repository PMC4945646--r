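#' Pan-Tompkins R-peak detection
#'
#' Classic QRS detection chain: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, then adaptive dual thresholds
#' on the integrated signal with a 200-ms refractory period and search-back
#' at half threshold when an expected beat is missed. Each accepted detection
#' is refined to the R apex of the input signal. All thresholds adapt to the
#' running signal/noise peak estimates, so detection is invariant to overall
#' amplitude scaling.
#'
#' @param ecg Preprocessed ECG vector.
#' @param fs Sampling rate, >= 128 Hz.
#' @return An `r_peaks` object: list with `index` (sample indices, strictly
#'   increasing, gaps >= 200 ms), `time` (s) and `fs`.
#' @export
detect_r_peaks <- function(ecg, fs = 256) {
  assert_that(fs >= 128, "Pan-Tompkins expects >= 128 samples/s")
  assert_that(length(ecg) >= 2 * fs, "signal shorter than 2 s")
  if (stats::sd(ecg) == 0) {
    return(structure(list(index = integer(), time = numeric(), fs = fs),
                     class = "r_peaks"))
  }
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, ecg - mean(ecg))
  h_d <- c(1, 2, 0, -2, -1) * fs / 8
  xd <- stats::filter(xb, rev(h_d), sides = 2)
  xd[is.na(xd)] <- 0
  xs <- as.numeric(xd)^2
  w <- round(0.15 * fs)
  xi <- as.numeric(stats::filter(xs, rep(1 / w, w), sides = 2))
  xi[is.na(xi)] <- 0

  # candidate peaks of the integrated signal: local maxima that dominate
  # their 200-ms neighbourhood (noise ripple on the integration hump's
  # flanks must not pre-empt the hump's true peak)
  n <- length(xi)
  is_pk <- c(FALSE, diff(xi) > 0) & c(xi[-n] >= xi[-1], FALSE)
  cand <- which(is_pk)
  half_nb <- round(0.2 * fs)
  dominant <- vapply(cand, function(p) {
    xi[p] >= max(xi[max(1L, p - half_nb):min(n, p + half_nb)])
  }, logical(1))
  cand <- cand[dominant]
  if (length(cand) == 0) {
    return(structure(list(index = integer(), time = numeric(), fs = fs),
                     class = "r_peaks"))
  }

  refract <- round(0.2 * fs)
  spki <- max(xi[seq_len(min(n, 2 * fs))]) / 3
  npki <- mean(xi[seq_len(min(n, 2 * fs))]) / 2
  thr1 <- npki + 0.25 * (spki - npki)
  beats <- integer()
  rr_recent <- numeric()

  accept <- function(p) {
    beats <<- c(beats, p)
    spki <<- 0.125 * xi[p] + 0.875 * spki
    if (length(beats) >= 2) {
      rr <- diff(utils::tail(beats, 9))
      rr_recent <<- utils::tail(rr, 8)
    }
    thr1 <<- npki + 0.25 * (spki - npki)
  }

  for (p in cand) {
    if (length(beats) > 0 && p - beats[length(beats)] < refract) next
    if (xi[p] > thr1) {
      accept(p)
    } else {
      npki <- 0.125 * xi[p] + 0.875 * npki
      thr1 <- npki + 0.25 * (spki - npki)
      # search-back: have we overshot 1.66x the recent RR average?
      if (length(rr_recent) > 0 && length(beats) > 0) {
        if (p - beats[length(beats)] > 1.66 * mean(rr_recent)) {
          window <- cand[cand > beats[length(beats)] + refract & cand <= p]
          if (length(window) > 0) {
            best <- window[which.max(xi[window])]
            if (xi[best] > 0.5 * thr1) accept(best)
          }
        }
      }
    }
  }
  if (length(beats) == 0) {
    return(structure(list(index = integer(), time = numeric(), fs = fs),
                     class = "r_peaks"))
  }

  # refine to the R apex of the input ECG near each integrated peak; the
  # integrator delays the QRS by about half the window plus the derivative
  half <- round(0.15 * fs)
  apex <- vapply(beats, function(p) {
    lo <- max(1L, p - 2L * half)
    hi <- min(length(ecg), p + round(0.05 * fs))
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  apex <- sort(unique(apex))
  # enforce the refractory on the refined apexes
  if (length(apex) > 1) {
    keep <- c(TRUE, diff(apex) >= refract)
    apex <- apex[keep]
  }
  structure(list(index = apex, time = apex / fs, fs = fs),
            class = "r_peaks")
}

#' @export
print.r_peaks <- function(x, ...) {
  cat(sprintf("<r_peaks> %d peaks @ %g Hz\n", length(x$index), x$fs))
  invisible(x)
}

#' Build an RR tachogram
#'
#' Converts detected R-peaks into beat-to-beat RR intervals and applies a
#' deterministic artifact rule (the automated stand-in for expert review):
#' an interval is excluded when it lies outside 300-2000 ms or deviates by
#' more than 20% from the local 5-beat running median.
#'
#' @param rpeaks An `r_peaks` object (>= 3 peaks).
#' @return A `tachogram` tibble: `time` (s, interval end), `rr_ms`, `kept`.
#' @export
build_tachogram <- function(rpeaks) {
  assert_that(length(rpeaks$index) >= 3, "need at least 3 peaks")
  t <- rpeaks$time
  rr <- diff(t) * 1000
  tt <- t[-1]
  med <- stats::runmed(rr, 5, endrule = "median")
  kept <- rr >= 300 & rr <= 2000 & abs(rr - med) <= 0.2 * med
  assert_that(sum(kept) >= 2, "fewer than 2 retained intervals")
  out <- tibble::tibble(time = tt, rr_ms = rr, kept = kept)
  class(out) <- c("tachogram", class(out))
  out
}

# Retained intervals of a tachogram (or a plain tibble slice of one).
tacho_kept <- function(tachogram) {
  tachogram[tachogram$kept, , drop = FALSE]
}

# Restrict a tachogram to intervals ending inside [start, end].
tacho_window <- function(tachogram, start, end) {
  out <- tachogram[tachogram$time >= start & tachogram$time <= end, ,
                   drop = FALSE]
  class(out) <- class(tachogram)
  out
}

#' Time-domain HRV metrics
#'
#' Eleven metrics of the retained RR intervals: max, min, mean, median and
#' SD of RR; SDANN-type SD of 30-s-window RR means (`t_SDANN`; missing when
#' fewer than two whole windows fit, e.g. on a single 30-s ad); RMSSD; the
#' count (`t_RR50`) and fraction (`t_pRR50`) of successive differences
#' larger than 50 ms; and mean/SD of instantaneous heart rate (beats/min).
#'
#' @param tachogram A `tachogram`.
#' @param sdann_window SDANN window length in seconds (default 30).
#' @return Named numeric vector of length 11.
#' @export
hrv_time_features <- function(tachogram, sdann_window = 30) {
  k <- tacho_kept(tachogram)
  rr <- k$rr_ms
  n <- length(rr)
  assert_that(n >= 2, "need at least 2 retained intervals")
  d <- diff(rr)
  hr <- 60000 / rr
  # windowed RR means over the covered span
  t0 <- min(k$time)
  span <- max(k$time) - t0
  n_win <- floor(span / sdann_window)
  sdann <- NA_real_
  if (n_win >= 2) {
    wm <- vapply(seq_len(n_win), function(w) {
      sel <- k$time >= t0 + (w - 1) * sdann_window &
        k$time < t0 + w * sdann_window
      if (!any(sel)) NA_real_ else mean(rr[sel])
    }, numeric(1))
    wm <- wm[is.finite(wm)]
    if (length(wm) >= 2) sdann <- stats::sd(wm)
  }
  rr50 <- sum(abs(d) > 50)
  c(t_maxRR = max(rr), t_minRR = min(rr), t_meanRR = mean(rr),
    t_medianRR = stats::median(rr), t_SDRR = stats::sd(rr),
    t_SDANN = sdann,
    t_RMSSD = if (n >= 2) sqrt(mean(d^2)) else NA_real_,
    t_RR50 = rr50, t_pRR50 = rr50 / (n - 1),
    t_meanHR = mean(hr), t_sdHR = stats::sd(hr))
}

# ---------------------------------------------------------------------------
# Spectral estimation on the tachogram

hrv_bands <- function() {
  tibble::tibble(band = c("ULF", "VLF", "LF", "HF"),
                 lo = c(0, 0.033, 0.04, 0.15),
                 hi = c(0.033, 0.04, 0.15, 0.4))
}

# Welch PSD of the RR series after cubic-spline resampling to 4 Hz.
rr_welch_psd <- function(time, rr, resample_fs = 4) {
  sp <- stats::spline(time, rr, xout = seq(min(time), max(time),
                                           by = 1 / resample_fs))
  x <- sp$y - mean(sp$y)
  n_window <- min(length(x), 1024L)
  welch_psd(x, resample_fs, n_window = n_window, overlap = 0.5)
}

# Lomb-Scargle periodogram of the unevenly sampled RR series, scaled to a
# one-sided density comparable in use (band ratios, peaks) to the Welch path.
rr_lomb_psd <- function(time, rr, f_max = 0.4, n_freq = 256) {
  x <- rr - mean(rr)
  n <- length(x)
  span <- max(time) - min(time)
  freq <- seq(1 / (2 * span), f_max, length.out = n_freq)
  pw <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * time)), sum(cos(2 * w * time))) / (2 * w)
    ct <- cos(w * (time - tau))
    st <- sin(w * (time - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  # normalize so the integral over frequency approximates the variance
  dens <- pw * 2 * span / n
  tibble::tibble(freq = freq, psd = dens)
}

spectral_metrics_from_psd <- function(spec) {
  bands <- hrv_bands()
  df <- mean(diff(spec$freq))
  a <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- spec$freq > bands$lo[b] & spec$freq <= bands$hi[b]
    if (!any(sel)) 0 else sum(spec$psd[sel]) * df
  }, numeric(1))
  names(a) <- bands$band
  pk <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- which(spec$freq > bands$lo[b] & spec$freq <= bands$hi[b])
    if (length(sel) == 0) NA_real_ else spec$freq[sel[which.max(spec$psd[sel])]]
  }, numeric(1))
  total <- sum(a)
  lf <- a[["LF"]]
  hf <- a[["HF"]]
  c(peakULF = pk[1], peakVLF = pk[2], peakLF = pk[3], peakHF = pk[4],
    aULF = a[[1]], aVLF = a[[2]], aLF = lf, aHF = hf, aTotal = total,
    pLF = if (total > 0) 100 * lf / total else NA_real_,
    pHF = if (total > 0) 100 * hf / total else NA_real_,
    nLF = if (lf + hf > 0) lf / (lf + hf) else NA_real_,
    nHF = if (lf + hf > 0) hf / (lf + hf) else NA_real_,
    LFHF = if (hf > 0) lf / hf else NA_real_)
}

#' Frequency-domain HRV metrics
#'
#' Fourteen metrics per spectral estimator: band peak frequencies, absolute
#' band powers (ms^2) for ULF/VLF/LF/HF, total power, percentage and
#' normalized LF/HF powers, and the LF/HF ratio. The Welch path resamples
#' the tachogram to 4 Hz with a cubic spline first; the Lomb-Scargle path
#' works on the raw unevenly sampled intervals. ULF and VLF are retained as
#' features even though they are physiologically meaningful only in long
#' registrations.
#'
#' @param tachogram A `tachogram`.
#' @param method `"welch"` or `"lomb"`.
#' @param min_intervals,min_span_s Minimum data requirements; below them all
#'   14 entries are missing.
#' @return Named numeric vector of length 14, prefixed `fw_` or `fl_`.
#' @export
hrv_spectral_features <- function(tachogram, method = c("welch", "lomb"),
                                  min_intervals = 8, min_span_s = 10) {
  method <- match.arg(method)
  prefix <- if (method == "welch") "fw_" else "fl_"
  k <- tacho_kept(tachogram)
  metric_names <- c("peakULF", "peakVLF", "peakLF", "peakHF", "aULF", "aVLF",
                    "aLF", "aHF", "aTotal", "pLF", "pHF", "nLF", "nHF",
                    "LFHF")
  empty <- stats::setNames(rep(NA_real_, 14), paste0(prefix, metric_names))
  if (nrow(k) < min_intervals ||
      (max(k$time) - min(k$time)) < min_span_s) {
    return(empty)
  }
  spec <- if (method == "welch") {
    rr_welch_psd(k$time, k$rr_ms)
  } else {
    rr_lomb_psd(k$time, k$rr_ms)
  }
  m <- spectral_metrics_from_psd(spec)
  stats::setNames(m, paste0(prefix, metric_names))
}

#' Time-frequency HRV metrics
#'
#' The fourteen Welch-path spectral metrics computed on 30-s tachogram
#' windows with 50% overlap and averaged across windows. With a single
#' full-length window this reduces exactly to [hrv_spectral_features()].
#'
#' @param tachogram A `tachogram`.
#' @param window_s Window length in seconds (default 30).
#' @return Named numeric vector of length 14, prefixed `tf_`.
#' @export
hrv_time_frequency_features <- function(tachogram, window_s = 30) {
  k <- tacho_kept(tachogram)
  metric_names <- c("peakULF", "peakVLF", "peakLF", "peakHF", "aULF", "aVLF",
                    "aLF", "aHF", "aTotal", "pLF", "pHF", "nLF", "nHF",
                    "LFHF")
  empty <- stats::setNames(rep(NA_real_, 14), paste0("tf_", metric_names))
  if (nrow(k) < 4) return(empty)
  span <- max(k$time) - min(k$time)
  t0 <- min(k$time)
  if (span <= window_s) {
    starts <- t0
  } else {
    starts <- seq(t0, t0 + span - window_s, by = window_s / 2)
  }
  per_win <- lapply(starts, function(s) {
    win <- tacho_window(tachogram, s, min(s + window_s, t0 + span))
    hrv_spectral_features(win, "welch")
  })
  mat <- do.call(rbind, per_win)
  m <- colMeans(mat, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  stats::setNames(m, paste0("tf_", metric_names))
}

#' Sample entropy
#'
#' Negative log conditional probability that runs matching for `m` points
#' within tolerance `r` still match at `m + 1` points. Zero for a constant
#' (perfectly regular) series; larger values mean more new information per
#' sample. Self-matches are excluded.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return Non-negative entropy, or `NA` when no template matches exist.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1) return(NA_real_)
  if (stats::sd(x) == 0) return(0)
  count_matches <- function(mm) {
    n_t <- n - mm + 1L
    emb <- sapply(seq_len(mm), function(j) x[j:(j + n_t - 1L)])
    emb <- matrix(emb, nrow = n_t)
    cnt <- 0L
    for (i in seq_len(n_t - 1L)) {
      d <- abs(emb[(i + 1L):n_t, , drop = FALSE] -
               matrix(emb[i, ], n_t - i, mm, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1)
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

#' Nonlinear HRV metrics
#'
#' Poincare-plot axes and sample entropy: `SD1^2 = Var(diff(RR)) / 2` (short
#' -term, minor axis), `SD2^2 = 2 Var(RR) - SD1^2` (long-term, major axis),
#' and [sample_entropy()] with `m = 2`, `r = 0.2 sd(RR)`.
#'
#' @param tachogram A `tachogram` with >= 10 retained intervals
#'   (>= 50 recommended for stable entropy).
#' @return Named numeric vector `nl_SD1`, `nl_SD2`, `nl_SampEn`.
#' @export
hrv_nonlinear_features <- function(tachogram) {
  rr <- tacho_kept(tachogram)$rr_ms
  if (length(rr) < 3) {
    return(c(nl_SD1 = NA_real_, nl_SD2 = NA_real_, nl_SampEn = NA_real_))
  }
  vd <- stats::var(diff(rr))
  vr <- stats::var(rr)
  sd1 <- sqrt(max(vd / 2, 0))
  sd2 <- sqrt(max(2 * vr - vd / 2, 0))
  c(nl_SD1 = sd1, nl_SD2 = sd2, nl_SampEn = sample_entropy(rr))
}

#' The 56-metric HRV battery
#'
#' Concatenates the time-domain (11), Welch frequency-domain (14),
#' Lomb-Scargle frequency-domain (14), time-frequency (14) and nonlinear (3)
#' metrics into one named vector of 56 values. Metrics that cannot be
#' computed on the given data are missing but never dropped, so the vector
#' length and names are stable.
#'
#' @param tachogram A `tachogram`.
#' @return Named numeric vector, length 56.
#' @export
hrv_feature_vector <- function(tachogram) {
  out <- c(hrv_time_features(tachogram),
           hrv_spectral_features(tachogram, "welch"),
           hrv_spectral_features(tachogram, "lomb"),
           hrv_time_frequency_features(tachogram),
           hrv_nonlinear_features(tachogram))
  stopifnot(length(out) == 56)
  out
}
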