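#' Kurtosis (fourth standardized moment)
#'
#' Plain, non-excess kurtosis `K = mu4 / sigma^4` computed with population
#' moments. A Gaussian signal has `K = 3`; spiky artifact-laden channels have
#' much larger values. A zero-variance input marks a degenerate channel and
#' yields `NA` rather than an error.
#'
#' @param x Numeric vector, length >= 4.
#' @return Dimensionless kurtosis, or `NA_real_` for constant input.
#' @export
#' @examples
#' kurtosis_coef(rep(c(-1, 1), 50)) # two-point symmetric: exactly 1
kurtosis_coef <- function(x) {
  assert_that(length(x) >= 4, "kurtosis needs at least 4 samples")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    return(NA_real_)
  }
  mean((x - mu)^4) / m2^2
}

#' Detect corrupted EEG channels
#'
#' A channel is rejected when its kurtosis is an outlier across the montage
#' (|robust z| above `kurtosis_z_threshold`) or when it is flat for more
#' than `flat_fraction_threshold` of the recording. "Flat" samples are those
#' whose absolute first difference is below 1e-6 of the channel's
#' interquartile range.
#'
#' The outlier statistic is the median of the channel's intra-epoch (1-s)
#' kurtosis values rather than the kurtosis of the whole trace: sparse
#' physiological transients such as blinks inflate whole-signal kurtosis
#' enormously on frontal channels, and a QC that flags them would hand the
#' downstream ICA a montage with its blink carriers interpolated away. A
#' genuinely corrupted channel is spiky in most epochs and keeps a high
#' median. The whole-signal kurtosis (the fourth standardized moment of the
#' full trace) is still reported per channel.
#'
#' @param eeg Matrix, channels x samples, with channel rownames.
#' @param fs Sampling rate, used to form the 1-s kurtosis epochs.
#' @param kurtosis_z_threshold Robust z cutoff (default 3).
#' @param flat_fraction_threshold Maximum tolerated flat fraction (default
#'   0.10).
#' @return A `channel_qc` tibble: `channel`, `kurtosis` (whole signal),
#'   `kurtosis_epoch_median`, `robust_z`, `flat_fraction`, `rejected`.
#' @export
detect_bad_channels <- function(eeg, fs = 256, kurtosis_z_threshold = 3,
                                flat_fraction_threshold = 0.10) {
  assert_that(is.matrix(eeg) && nrow(eeg) >= 2, "need >= 2 channels")
  k <- apply(eeg, 1, kurtosis_coef)
  n_ep <- max(1L, floor(ncol(eeg) / fs))
  k_med <- apply(eeg, 1, function(x) {
    ke <- vapply(seq_len(n_ep), function(e) {
      seg <- x[((e - 1) * fs + 1):min(e * fs, length(x))]
      if (length(seg) >= 4) kurtosis_coef(seg) else NA_real_
    }, numeric(1))
    stats::median(ke, na.rm = TRUE)
  })
  flat <- apply(eeg, 1, function(x) {
    iqr <- stats::IQR(x)
    if (iqr == 0) return(1)
    mean(abs(diff(x)) < 1e-6 * iqr)
  })
  z <- robust_z(k_med)
  rejected <- (is.na(k_med) | abs(z) > kurtosis_z_threshold) |
    flat > flat_fraction_threshold
  out <- tibble::tibble(
    channel = rownames(eeg) %||% as.character(seq_len(nrow(eeg))),
    kurtosis = k, kurtosis_epoch_median = k_med, robust_z = z,
    flat_fraction = flat, rejected = rejected
  )
  class(out) <- c("channel_qc", class(out))
  out
}

#' Interpolate rejected channels
#'
#' Replaces each rejected channel with the inverse-distance-weighted average
#' of its 4 nearest good electrodes in the standard 10-20 layout.
#'
#' @param eeg Matrix, channels x samples, rownames matching
#'   [electrode_positions()].
#' @param report A `channel_qc` from [detect_bad_channels()].
#' @param k Number of good neighbours to average (default 4).
#' @return The matrix with rejected channels replaced.
#' @export
interpolate_channels <- function(eeg, report, k = 4) {
  bad <- report$channel[report$rejected]
  if (length(bad) == 0) return(eeg)
  good <- setdiff(rownames(eeg), bad)
  assert_that(length(good) >= 1, "all channels rejected; cannot interpolate")
  pos <- electrode_positions()
  coords <- as.matrix(pos[, c("x", "y")])
  rownames(coords) <- pos$channel
  for (ch in bad) {
    d <- sqrt(rowSums((coords[good, , drop = FALSE] -
                       matrix(coords[ch, ], length(good), 2,
                              byrow = TRUE))^2))
    nb <- names(sort(d))[seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[nb], 1e-9)
    w <- w / sum(w)
    eeg[ch, ] <- as.numeric(w %*% eeg[nb, , drop = FALSE])
  }
  eeg
}

#' Band-pass filter EEG
#'
#' Per-channel mean subtraction followed by a zero-phase (forward-backward)
#' Butterworth band-pass, 0.5-40 Hz by default.
#'
#' @param eeg Matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered matrix of the same shape.
#' @export
filter_eeg <- function(eeg, fs = 256, lo = 0.5, hi = 40, order = 4) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  out <- eeg
  for (c in seq_len(nrow(eeg))) {
    x <- eeg[c, ] - mean(eeg[c, ])
    out[c, ] <- signal::filtfilt(bf, x)
  }
  out
}

#' Segment EEG into 1-s epochs and reject noisy ones
#'
#' The recording is cut into contiguous non-overlapping 1-second epochs; an
#' epoch is dropped when, for any channel, the intra-epoch kurtosis is an
#' outlier (|robust z| above `z_threshold`) relative to that channel's
#' distribution across epochs. The default cutoff of 8 targets severely
#' damaged epochs only: ordinary blink epochs must survive to this stage so
#' that the ICA can isolate them, and clean recordings should lose well
#' under 5% of their epochs.
#'
#' @param eeg Matrix, channels x samples.
#' @param fs Sampling rate (samples per epoch).
#' @param z_threshold Robust z cutoff (default 8).
#' @return An `epoched_eeg`: list with `data` (array epochs x channels x
#'   fs), `keep` (logical per epoch), `fs`, and `sample_mask` (logical per
#'   original sample; FALSE inside rejected epochs or beyond the last whole
#'   epoch).
#' @export
epoch_and_reject <- function(eeg, fs = 256, z_threshold = 8) {
  n <- ncol(eeg)
  n_ep <- floor(n / fs)
  assert_that(n_ep >= 1, "need at least one second of data")
  nch <- nrow(eeg)
  k <- matrix(NA_real_, n_ep, nch)
  data <- array(NA_real_, c(n_ep, nch, fs),
                dimnames = list(NULL, rownames(eeg), NULL))
  for (e in seq_len(n_ep)) {
    seg <- eeg[, ((e - 1) * fs + 1):(e * fs), drop = FALSE]
    data[e, , ] <- seg
    k[e, ] <- apply(seg, 1, kurtosis_coef)
  }
  z <- apply(k, 2, robust_z)
  z <- matrix(z, n_ep, nch)
  bad <- apply(z, 1, function(r) any(abs(r) > z_threshold, na.rm = TRUE))
  keep <- !bad
  sample_mask <- rep(FALSE, n)
  for (e in which(keep)) {
    sample_mask[((e - 1) * fs + 1):(e * fs)] <- TRUE
  }
  structure(list(data = data, keep = keep, fs = fs,
                 sample_mask = sample_mask),
            class = "epoched_eeg")
}

# ---------------------------------------------------------------------------
# ICA

# Deflation FastICA with tanh contrast on whitened data. Components are
# extracted one at a time in order of decreasing non-Gaussianity, each with
# its own convergence test; once a direction fails to converge the residual
# subspace is treated as Gaussian noise and completed with an orthonormal
# basis (such components are never artifact candidates). X: channels x
# samples. Returns unmixing W (components x channels), mixing A (channels x
# components) with A %*% W = identity on the retained subspace, a per-
# component `component_converged` flag, and `converged` = at least one
# genuine independent component was found.
fast_ica <- function(X, n_comp = nrow(X), seed = 1L, max_iter = 200,
                     tol = 1e-4) {
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / n
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-10
  n_comp <- min(n_comp, sum(keep))
  D <- eig$values[seq_len(n_comp)]
  E <- eig$vectors[, seq_len(n_comp), drop = FALSE]
  whiten <- diag(1 / sqrt(D), n_comp) %*% t(E)
  dewhiten <- E %*% diag(sqrt(D), n_comp)
  Z <- whiten %*% Xc

  W <- matrix(0, n_comp, n_comp)
  comp_ok <- logical(n_comp)
  inits <- with_local_seed(seed,
                           matrix(stats::rnorm(n_comp^2), n_comp, n_comp))
  found <- 0L
  for (c in seq_len(n_comp)) {
    w <- inits[, c]
    if (found > 0) {
      Wf <- W[seq_len(found), , drop = FALSE]
      w <- w - as.numeric(t(Wf) %*% (Wf %*% w))
    }
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- as.numeric(w %*% Z)
      g <- tanh(wz)
      w_new <- as.numeric(Z %*% g) / n - mean(1 - g^2) * w
      if (found > 0) {
        Wf <- W[seq_len(found), , drop = FALSE]
        w_new <- w_new - as.numeric(t(Wf) %*% (Wf %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) break
      w_new <- w_new / nrm
      delta <- 1 - abs(sum(w_new * w))
      w <- w_new
      if (delta < tol) {
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    found <- found + 1L
    W[found, ] <- w
    comp_ok[found] <- TRUE
  }
  if (found < n_comp) {
    # orthonormal completion of the unidentified (near-Gaussian) subspace
    basis <- diag(n_comp)
    if (found > 0) {
      Wf <- W[seq_len(found), , drop = FALSE]
      basis <- basis - t(Wf) %*% Wf
    }
    q <- qr(basis)
    Q <- qr.Q(q)[, seq_len(n_comp - found), drop = FALSE]
    W[(found + 1L):n_comp, ] <- t(Q)
  }
  unmixing <- W %*% whiten          # components x channels
  mixing <- dewhiten %*% t(W)       # channels x components
  list(unmixing = unmixing, mixing = mixing, center = mu,
       component_converged = comp_ok, converged = any(comp_ok))
}

#' Detect and remove artifact components
#'
#' Runs a seeded ICA on the (kept) EEG samples and scores every component for
#' blink-likeness: the product of its frontal spatial concentration (share of
#' mixing-vector energy on the 12 frontal electrodes), its temporal kurtosis,
#' and its maximum-to-median epoch-variance ratio. Log-scores are split by
#' 1-D 2-means clustering; the upper cluster is flagged only when it is
#' clearly separated from the lower one (gap above twice the pooled
#' within-cluster spread), so clean recordings yield zero rejections. Flagged
#' components are zeroed before back-projection.
#'
#' @param eeg Matrix, channels x samples (band-pass filtered).
#' @param fs Sampling rate.
#' @param sample_mask Optional logical mask of samples to use when fitting
#'   the decomposition (e.g. from [epoch_and_reject()]).
#' @param seed Seed for the ICA initialization.
#' @param min_gap Minimum separation (in pooled within-cluster SD units)
#'   between score clusters before anything is flagged.
#' @param min_kurtosis,min_frontal Absolute floors a component must exceed
#'   to be an artifact candidate: blinks are temporally spiky (kurtosis
#'   well above the Gaussian 3) and frontally concentrated; ordinary
#'   rhythmic or noise components are not, which keeps clean recordings at
#'   zero rejections.
#' @return List with `eeg` (cleaned matrix) and `decomposition` (unmixing,
#'   mixing, per-component `scores` tibble, `rejected` indices,
#'   `converged`).
#' @export
reject_artifact_components <- function(eeg, fs = 256, sample_mask = NULL,
                                       seed = 1L, min_gap = 2,
                                       min_kurtosis = 5, min_frontal = 0.4) {
  assert_that(ncol(eeg) >= nrow(eeg), "need at least as many samples as channels")
  fit_idx <- if (is.null(sample_mask)) seq_len(ncol(eeg)) else which(sample_mask)
  # fitting the decomposition on ~50k samples is ample for 30 components
  # and keeps long sessions tractable; cleaning still uses every sample
  max_fit <- 50000L
  if (length(fit_idx) > max_fit) {
    fit_idx <- fit_idx[round(seq(1, length(fit_idx), length.out = max_fit))]
  }
  ica <- fast_ica(eeg[, fit_idx, drop = FALSE], seed = seed)
  if (!ica$converged) {
    warning("ICA did not converge; returning input unchanged")
    return(list(eeg = eeg, decomposition = list(
      unmixing = ica$unmixing, mixing = ica$mixing, scores = NULL,
      rejected = integer(), converged = FALSE)))
  }
  S_fit <- ica$unmixing %*% (eeg[, fit_idx, drop = FALSE] - ica$center)
  frontal <- rownames(eeg) %in% frontal_channels()
  n_comp <- nrow(ica$unmixing)
  spatial <- vapply(seq_len(n_comp), function(c) {
    a <- ica$mixing[, c]
    sum(a[frontal]^2) / sum(a^2)
  }, numeric(1))
  temporal <- apply(S_fit, 1, kurtosis_coef)
  ep_var <- apply(S_fit, 1, function(s) {
    n_ep <- floor(length(s) / fs)
    if (n_ep < 2) return(1)
    v <- vapply(seq_len(n_ep),
                function(e) stats::var(s[((e - 1) * fs + 1):(e * fs)]),
                numeric(1))
    max(v) / max(stats::median(v), 1e-12)
  })
  score <- pmax(spatial, 1e-6) * pmax(temporal, 1e-6) * pmax(ep_var, 1e-6)
  ls <- log(score)
  rejected <- integer()
  if (stats::sd(ls) > 1e-8) {
    km <- stats::kmeans(ls, centers = range(ls))
    hi <- which.max(km$centers)
    within_sd <- sqrt(max(km$tot.withinss / max(length(ls) - 2, 1), 1e-12))
    gap <- abs(diff(as.numeric(km$centers)))
    if (gap > min_gap * within_sd && gap > 1) {
      rejected <- which(km$cluster == hi)
      # only genuine (converged) independent components that look like
      # blinks (spiky and frontal) can be artifacts
      rejected <- rejected[ica$component_converged[rejected] &
                           temporal[rejected] > min_kurtosis &
                           spatial[rejected] > min_frontal]
    }
  }
  cleaned <- eeg
  if (length(rejected) > 0) {
    S_all <- ica$unmixing %*% (eeg - ica$center)
    cleaned <- cleaned -
      ica$mixing[, rejected, drop = FALSE] %*%
      S_all[rejected, , drop = FALSE]
  }
  scores <- tibble::tibble(component = seq_len(n_comp),
                           frontal_concentration = spatial,
                           temporal_kurtosis = temporal,
                           max_epoch_variance = ep_var,
                           score = score,
                           rejected = seq_len(n_comp) %in% rejected)
  list(eeg = cleaned,
       decomposition = list(unmixing = ica$unmixing, mixing = ica$mixing,
                            scores = scores, rejected = rejected,
                            converged = TRUE))
}

#' Full EEG preprocessing chain
#'
#' Mean subtraction and 0.5-40 Hz band-pass, kurtosis/flatness channel QC
#' with neighbour interpolation, 1-s epoching with kurtosis-based epoch
#' rejection, and (optionally) ICA blink-component removal.
#'
#' @param eeg Matrix channels x samples with 10-20 rownames.
#' @param fs Sampling rate.
#' @param ica Run the artifact-component stage (default TRUE).
#' @param seed Seed for the ICA.
#' @param ... Passed to [detect_bad_channels()].
#' @return List: `eeg` (cleaned), `sample_mask`, `qc` (channel report),
#'   `epochs` (`epoched_eeg`), `decomposition` (or NULL).
#' @export
preprocess_eeg <- function(eeg, fs = 256, ica = TRUE, seed = 1L, ...) {
  x <- filter_eeg(eeg, fs)
  qc <- detect_bad_channels(x, fs = fs, ...)
  x <- interpolate_channels(x, qc)
  ep <- epoch_and_reject(x, fs)
  dec <- NULL
  if (ica) {
    res <- reject_artifact_components(x, fs, sample_mask = ep$sample_mask,
                                      seed = seed)
    x <- res$eeg
    dec <- res$decomposition
  }
  list(eeg = x, sample_mask = ep$sample_mask, qc = qc, epochs = ep,
       decomposition = dec)
}

# ---------------------------------------------------------------------------
# ECG and morphological filtering

# Zero-phase application of a linear-phase FIR filter: FFT convolution with
# reflection padding, compensating the (L-1)/2 group delay.
fir_zero_phase <- function(x, b) {
  l <- length(b)
  half <- (l - 1L) %/% 2L
  pad <- min(l, length(x) - 1L)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  y <- signal::fftfilt(b, c(xp, numeric(l)))
  y <- y[(pad + half + 1):(pad + half + length(x))]
  y
}

#' Preprocess an ECG trace
#'
#' Mean subtraction, linear-phase FIR high-pass at 0.5 Hz (baseline wander),
#' a 50 Hz notch (powerline), and a low-pass at 65 Hz (muscle noise). All
#' stages are zero-phase in effect so the QRS morphology and R-peak latency
#' are preserved.
#'
#' @param ecg Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return Filtered vector of the same length.
#' @export
preprocess_ecg <- function(ecg, fs = 256) {
  x <- ecg - mean(ecg)
  # high-pass: long FIR for a narrow transition around 0.5 Hz
  n_hp <- min(4096L, 2L * (floor(length(x) / 4) %/% 2L))
  if (n_hp >= 64) {
    b_hp <- signal::fir1(n_hp, 0.5 / (fs / 2), type = "high")
    x <- fir_zero_phase(x, b_hp)
  }
  # 50 Hz notch (zero-phase biquad, narrow so the QRS band is untouched)
  w0 <- 2 * pi * 50 / fs
  r <- 0.99
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b) # unit DC gain
  x <- signal::filtfilt(signal::Arma(b = b, a = a), x)
  # low-pass at 65 Hz
  if (fs / 2 > 65) {
    b_lp <- signal::fir1(256, 65 / (fs / 2), type = "low")
    x <- fir_zero_phase(x, b_lp)
  }
  x
}

#' Morphological smoothing filter
#'
#' Grayscale opening followed by closing with a flat structuring element.
#' Ripple narrower than the element is removed while the locations of wider
#' peaks (sudomotor responses, breaths) are preserved; monotone signals pass
#' unchanged.
#'
#' @param x Numeric vector.
#' @param element_width_s Structuring element width in seconds.
#' @param fs Sampling rate in Hz.
#' @return Smoothed vector.
#' @export
morphological_filter <- function(x, element_width_s, fs) {
  w <- max(2L, round(element_width_s * fs))
  if (w %% 2L == 0L) w <- w + 1L
  open <- running_extreme(running_extreme(x, w, pmin), w, pmax)
  running_extreme(running_extreme(open, w, pmax), w, pmin)
}
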