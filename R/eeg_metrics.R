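#' EEG frequency bands
#'
#' The six canonical bands: delta 1-3, theta 4-7, alpha 8-12, beta 13-24,
#' extended beta 25-40 and gamma 25-100 Hz. Because the preprocessing chain
#' low-passes at 40 Hz, the gamma band carries essentially no energy above
#' 40 Hz; it is computed over its nominal range regardless, which makes it
#' numerically close to extended beta on cleaned data.
#'
#' @return Tibble with `band`, `lo`, `hi` (Hz) and `center` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "beta_ext", "gamma"),
    lo = c(1, 4, 8, 13, 25, 25),
    hi = c(3, 7, 12, 24, 40, 100),
    center = (c(1, 4, 8, 13, 25, 25) + c(3, 7, 12, 24, 40, 100)) / 2
  )
}

# Zero-phase Butterworth band-pass of a channels x samples matrix, band
# edges clipped to the representable range.
band_filter <- function(eeg, fs, lo, hi, order = 4) {
  hi <- min(hi, 0.98 * fs / 2)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  t(apply(eeg, 1, function(x) signal::filtfilt(bf, x)))
}

#' Global field power
#'
#' Instantaneous dispersion of scalp potentials over an electrode set,
#' computed per time sample as
#' `GFP = sqrt( sum_i sum_j (u_i - u_j)^2 / Ne )`,
#' the root of the mean-per-electrode sum of all pairwise potential
#' differences. Algebraically this equals `sqrt(2 * sum_i (u_i - mean(u))^2)`.
#' It is zero exactly when all electrodes are equipotential, and positively
#' homogeneous in the potentials.
#'
#' @param eeg Matrix, electrodes x samples (already band-filtered for
#'   band-specific GFP). At least 2 electrodes.
#' @return Numeric vector, one non-negative value per sample (microvolts).
#' @export
#' @examples
#' global_field_power(matrix(c(0, 2), nrow = 2)) # 2
global_field_power <- function(eeg) {
  assert_that(is.matrix(eeg) && nrow(eeg) >= 2,
              "GFP needs at least two electrodes")
  ne <- nrow(eeg)
  cs <- colSums(eeg)
  ss <- colSums(eeg^2)
  sqrt(pmax(2 * ss - 2 * cs^2 / ne, 0))
}

#' Baseline-standardized GFP (Zscore index)
#'
#' Standardizes a stimulus-period GFP series by the mean and standard
#' deviation of the GFP over the 2-minute documentary baseline preceding the
#' stimulus block: `Z_i = (GFP_i - mean(GFP_B)) / sd(GFP_B)`. Invariant to
#' common rescaling of stimulus and baseline.
#'
#' @param gfp_stimulus GFP samples during the stimulus.
#' @param gfp_baseline GFP samples during the preceding 2-min baseline.
#' @return Dimensionless vector, same length as `gfp_stimulus`.
#' @export
zscore_series <- function(gfp_stimulus, gfp_baseline) {
  mb <- mean(gfp_baseline, na.rm = TRUE)
  sb <- stats::sd(gfp_baseline[!is.na(gfp_baseline)])
  assert_that(is.finite(sb) && sb > 0, "baseline GFP has zero variance")
  (gfp_stimulus - mb) / sb
}

#' Count supra-threshold Zscore peaks
#'
#' A peak is one maximal contiguous excursion of the Zscore series at or
#' above the threshold (default 3, i.e. p < 0.05 under the fitted Gaussian),
#' counted once however long it lasts. A peak is attributed to the brand when
#' its apex falls inside a brand-exposure window.
#'
#' @param zscore Zscore series.
#' @param times Time stamp (s) of each sample, on the same clock as
#'   `brand_windows`.
#' @param brand_windows List of `c(start, end)` intervals (end exclusive).
#' @param threshold Peak threshold (default 3).
#' @return Named list `pn_total`, `pn_brand`.
#' @export
count_peaks <- function(zscore, times, brand_windows, threshold = 3) {
  assert_that(threshold > 0, "threshold must be positive")
  above <- !is.na(zscore) & zscore >= threshold
  if (!any(above)) {
    return(list(pn_total = 0L, pn_brand = 0L))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pn_total <- length(runs)
  pn_brand <- 0L
  for (run in runs) {
    idx <- starts[run]:ends[run]
    apex <- idx[which.max(zscore[idx])]
    t_apex <- times[apex]
    in_brand <- any(vapply(brand_windows,
                           function(w) t_apex >= w[1] && t_apex < w[2],
                           logical(1)))
    if (in_brand) pn_brand <- pn_brand + 1L
  }
  list(pn_total = pn_total, pn_brand = pn_brand)
}

#' Interest index
#'
#' Fraction of supra-threshold Zscore peaks whose apex falls inside the
#' brand-exposure windows of an ad: `II = PN_brand / PN_total`, missing when
#' no peaks occurred at all.
#'
#' @param pn_brand,pn_total Non-negative peak counts.
#' @return Value in `[0, 1]`, or `NA` when `pn_total` is 0.
#' @export
interest_index <- function(pn_brand, pn_total) {
  assert_that(pn_brand >= 0 && pn_total >= 0 && pn_brand <= pn_total,
              "need 0 <= pn_brand <= pn_total")
  if (pn_total == 0) {
    return(NA_real_)
  }
  pn_brand / pn_total
}

# Cubic smoothing spline envelope (smoothing parameter by generalized
# cross-validation).
smooth_envelope <- function(times, values) {
  ok <- is.finite(values)
  if (sum(ok) < 8) return(values)
  fit <- stats::smooth.spline(times[ok], values[ok], cv = FALSE)
  stats::predict(fit, times)$y
}

#' Memorization index group curves
#'
#' Each subject's stimulus-period GFP is normalized to sum to one over the
#' stimulus (`MI_t = GFP_t / sum_t GFP_t`), averaged within the remember and
#' forget groups, and smoothed with a cubic smoothing spline to extract the
#' envelope.
#'
#' @param per_subject_gfp Matrix subjects x time of stimulus-period GFP in
#'   theta or alpha band.
#' @param remember_flags Logical per subject.
#' @param band Band label, `"theta"` or `"alpha"`.
#' @param times Optional time axis (s), defaults to sample index.
#' @return A `group_curves` tibble: `time`, `value`, `group`
#'   (remember/forget), `band`, `index` = "MI". Empty groups are omitted and
#'   recorded in the `unavailable` attribute.
#' @export
memorization_curves <- function(per_subject_gfp, remember_flags,
                                band = c("theta", "alpha"), times = NULL) {
  band <- match.arg(band)
  times <- times %||% seq_len(ncol(per_subject_gfp))
  mi <- t(apply(per_subject_gfp, 1, function(g) g / sum(g)))
  build_group_curves(mi, remember_flags, c("remember", "forget"),
                     band, "MI", times)
}

#' Pleasantness index group curves
#'
#' Hemispheric asymmetry of frontal GFP: `PI = GFP_right - GFP_left`
#' averaged within the like and dislike groups, then smoothed. The left set
#' is Fp1, F7, F3, Fc5, Fc1 and the right set Fp2, F8, F4, Fc6, Fc2.
#'
#' @param per_subject_gfp_left,per_subject_gfp_right Matrices subjects x
#'   time of left- and right-frontal GFP.
#' @param like_flags Logical per subject.
#' @param band Band label.
#' @param times Optional time axis.
#' @return A `group_curves` tibble with `index` = "PI" and groups
#'   like/dislike.
#' @export
pleasantness_curves <- function(per_subject_gfp_left, per_subject_gfp_right,
                                like_flags, band = c("theta", "alpha"),
                                times = NULL) {
  band <- match.arg(band)
  times <- times %||% seq_len(ncol(per_subject_gfp_left))
  pi_mat <- per_subject_gfp_right - per_subject_gfp_left
  build_group_curves(pi_mat, like_flags, c("like", "dislike"),
                     band, "PI", times)
}

build_group_curves <- function(mat, flags, group_names, band, index, times) {
  pieces <- list()
  unavailable <- character()
  for (g in c(TRUE, FALSE)) {
    label <- if (g) group_names[1] else group_names[2]
    members <- which(flags == g)
    if (length(members) == 0) {
      unavailable <- c(unavailable, label)
      next
    }
    avg <- colMeans(mat[members, , drop = FALSE])
    pieces[[label]] <- tibble::tibble(
      time = times, value = smooth_envelope(times, avg),
      group = label, band = band, index = index)
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "unavailable") <- unavailable
  class(out) <- c("group_curves", class(out))
  out
}

#' Welch power spectral density
#'
#' Averaged periodogram over sliding windows: the signal is cut into
#' `n_window`-sample segments with the given overlap, each segment's
#' periodogram is `|FFT|^2 / N` (rectangular taper, as the periodogram is
#' defined), and the periodograms are averaged. Returned as a one-sided
#' density so that `sum(psd * df)` equals the signal's mean power.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param n_window Window length in samples (default 128, half a second of
#'   256-Hz EEG).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @param demean Subtract each segment's mean first (default TRUE).
#' @return Tibble `freq` (Hz), `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, n_window = 128, overlap = 0.5, demean = TRUE) {
  n <- length(x)
  assert_that(n >= n_window, "signal shorter than one Welch window")
  hop <- max(1L, round(n_window * (1 - overlap)))
  starts <- seq(1L, n - n_window + 1L, by = hop)
  acc <- numeric(n_window)
  for (s in starts) {
    seg <- x[s:(s + n_window - 1L)]
    if (demean) seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg))^2 / n_window
  }
  p <- acc / length(starts)
  # fold to one-sided density
  half <- floor(n_window / 2)
  freq <- (0:half) * fs / n_window
  dens <- p[1:(half + 1)] / fs
  if (n_window %% 2 == 0) {
    dens[2:half] <- dens[2:half] + rev(p[(half + 2):n_window]) / fs
  } else {
    dens[2:(half + 1)] <- dens[2:(half + 1)] + rev(p[(half + 2):n_window]) / fs
  }
  tibble::tibble(freq = freq, psd = dens)
}

#' Mean band power from the Welch periodogram
#'
#' Integrates the Welch density over `[lo, hi]`.
#'
#' @inheritParams welch_psd
#' @param lo,hi Band edges in Hz.
#' @return Mean power in the band (signal units squared).
#' @export
welch_band_power <- function(x, fs, lo, hi, n_window = 128, overlap = 0.5) {
  spec <- welch_psd(x, fs, n_window, overlap)
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= lo & spec$freq <= hi
  sum(spec$psd[sel]) * df
}

#' Brainrate
#'
#' Power-weighted mean of the band-centre frequencies over delta..beta; an
#' optional spectral summary not part of the canonical feature vectors.
#'
#' @param psd_by_band Named numeric: band powers for delta, theta, alpha,
#'   beta.
#' @return Frequency in Hz.
#' @export
brainrate <- function(psd_by_band) {
  bands <- eeg_bands()
  use <- c("delta", "theta", "alpha", "beta")
  p <- psd_by_band[use]
  assert_that(all(is.finite(p)) && sum(p) > 0, "band powers must be positive")
  centers <- bands$center[match(use, bands$band)]
  sum(p * centers) / sum(p)
}

# ---------------------------------------------------------------------------
# Per-instance EEG feature vectors

# Masked time average: samples in rejected epochs are excluded.
masked_mean <- function(x, mask = NULL) {
  if (!is.null(mask)) x[!mask] <- NA
  mean(x, na.rm = TRUE)
}

#' EEG feature vectors for one (subject, ad) instance
#'
#' Computes the three canonical EEG feature families from preprocessed EEG:
#'
#' * `gfp_zscore` (18): time-averaged GFP, Zscore and log(mean Zscore) in
#'   each of the six bands (frontal electrode set);
#' * `psd` (72): Welch mean band power for 6 bands x 12 frontal electrodes;
#' * `index` (8): mean theta/alpha Zscore, interest indexes on theta and
#'   beta Zscore series, and supra-threshold peak counts (total and brand)
#'   in theta and extended beta;
#' * `all` (98): their concatenation.
#'
#' @param eeg Preprocessed matrix channels x samples covering the whole
#'   session.
#' @param fs Sampling rate.
#' @param timeline The `session_timeline`.
#' @param ad_id Which ad to analyse.
#' @param sample_mask Optional per-sample keep mask from preprocessing.
#' @param peak_threshold Zscore peak threshold (default 3).
#' @return Named list of four named numeric vectors with lengths 18, 72, 8
#'   and 98.
#' @export
eeg_feature_vectors <- function(eeg, fs, timeline, ad_id,
                                sample_mask = NULL, peak_threshold = 3) {
  ads <- ad_blocks(timeline)
  row <- ads[ads$ad_id == ad_id, ]
  assert_that(nrow(row) == 1, "unknown ad_id")
  stim <- seq(round(row$onset * fs) + 1L,
              round((row$onset + row$duration) * fs))
  bl <- baseline_window(timeline, row$block)
  base <- seq(round(bl[1] * fs) + 1L, round(bl[2] * fs))
  fr <- intersect(frontal_channels(), rownames(eeg))
  assert_that(length(fr) == 12, "the 12 frontal channels are required")
  bands <- eeg_bands()
  t_stim <- stim / fs

  mask_stim <- if (is.null(sample_mask)) NULL else sample_mask[stim]
  mask_base <- if (is.null(sample_mask)) NULL else sample_mask[base]

  gfp_z <- numeric(0)
  z_series <- list()
  for (b in seq_len(nrow(bands))) {
    seg <- band_filter(eeg[fr, c(base, stim), drop = FALSE], fs,
                       bands$lo[b], bands$hi[b])
    nb <- length(base)
    g_base <- global_field_power(seg[, seq_len(nb), drop = FALSE])
    g_stim <- global_field_power(seg[, nb + seq_along(stim), drop = FALSE])
    if (!is.null(mask_base)) g_base[!mask_base] <- NA
    z <- zscore_series(g_stim, g_base)
    if (!is.null(mask_stim)) z[!mask_stim] <- NA
    z_series[[bands$band[b]]] <- z
    mean_g <- masked_mean(g_stim, mask_stim)
    mean_z <- mean(z, na.rm = TRUE)
    log_z <- if (is.finite(mean_z) && mean_z > 0) log(mean_z) else NA_real_
    v <- c(mean_g, mean_z, log_z)
    names(v) <- paste0(c("gfp_mean_", "z_mean_", "logz_mean_"),
                       bands$band[b])
    gfp_z <- c(gfp_z, v)
  }

  psd <- numeric(0)
  for (ch in fr) {
    seg <- eeg[ch, stim]
    for (b in seq_len(nrow(bands))) {
      p <- welch_band_power(seg, fs, bands$lo[b],
                            min(bands$hi[b], fs / 2))
      names(p) <- paste0("psd_", bands$band[b], "_", ch)
      psd <- c(psd, p)
    }
  }

  bw <- row$brand_windows[[1]]
  pk_theta <- count_peaks(z_series$theta, t_stim, bw, peak_threshold)
  pk_beta <- count_peaks(z_series$beta, t_stim, bw, peak_threshold)
  pk_bext <- count_peaks(z_series$beta_ext, t_stim, bw, peak_threshold)
  index <- c(
    mean_Theta = mean(z_series$theta, na.rm = TRUE),
    mean_Alfa = mean(z_series$alpha, na.rm = TRUE),
    Index_Theta = interest_index(pk_theta$pn_brand, pk_theta$pn_total),
    Index_Beta = interest_index(pk_beta$pn_brand, pk_beta$pn_total),
    Peaks_Theta = pk_theta$pn_total,
    Peaks_Brand_Theta = pk_theta$pn_brand,
    Peaks_Beta_Ext = pk_bext$pn_total,
    Peaks_Brand_Beta_Ext = pk_bext$pn_brand
  )

  list(gfp_zscore = gfp_z, psd = psd, index = index,
       all = c(gfp_z, psd, index))
}
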