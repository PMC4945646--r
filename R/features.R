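#' Extract all per-stimulus features for one subject
#'
#' Runs the full preprocessing and feature-extraction chain on a subject's
#' signal bundle and returns one feature row per ad for every signal family
#' present: `gsr` (10 features), `rsp` (6), `hrv` (56), and - when EEG was
#' recorded - `eeg_gfp_zscore` (18), `eeg_psd` (72) and `eeg_ind` (8).
#'
#' @param bundle A `signal_bundle`.
#' @param ica Run ICA blink removal in the EEG chain (default TRUE).
#' @param seed Seed for the ICA stage.
#' @return Named list of tibbles, each with `subject`, `ad`, `label` and the
#'   family's named feature columns.
#' @export
extract_subject_features <- function(bundle, ica = TRUE, seed = 1L) {
  timeline <- bundle$timeline
  ads <- ad_blocks(timeline)
  labels <- bundle$profile$ad_labels
  id_cols <- function() {
    tibble::tibble(subject = bundle$profile$subject_id, ad = ads$ad_id,
                   label = unname(labels[ads$ad_id]))
  }
  out <- list()

  if (!is.null(bundle$gsr)) {
    fs <- bundle$fs$gsr
    sm <- morphological_filter(bundle$gsr, 0.5, fs)
    rows <- lapply(seq_len(nrow(ads)), function(i) {
      seg <- sm[(round(ads$onset[i] * fs) + 1L):
                round((ads$onset[i] + ads$duration[i]) * fs)]
      gsr_features(seg, fs)
    })
    out$gsr <- dplyr::bind_cols(id_cols(),
                                tibble::as_tibble(do.call(rbind, rows)))
  }

  if (!is.null(bundle$rsp)) {
    fs <- bundle$fs$rsp
    sm <- morphological_filter(bundle$rsp, 0.25, fs)
    rows <- lapply(seq_len(nrow(ads)), function(i) {
      seg <- sm[(round(ads$onset[i] * fs) + 1L):
                round((ads$onset[i] + ads$duration[i]) * fs)]
      rsp_features(seg, fs)
    })
    out$rsp <- dplyr::bind_cols(id_cols(),
                                tibble::as_tibble(do.call(rbind, rows)))
  }

  if (!is.null(bundle$ecg)) {
    fs <- bundle$fs$ecg
    clean <- preprocess_ecg(bundle$ecg, fs)
    peaks <- detect_r_peaks(clean, fs)
    tacho <- build_tachogram(peaks)
    rows <- lapply(seq_len(nrow(ads)), function(i) {
      win <- tacho_window(tacho, ads$onset[i], ads$onset[i] + ads$duration[i])
      if (sum(win$kept) < 3) {
        return(stats::setNames(rep(NA_real_, 56),
                               names(hrv_feature_vector(tacho))))
      }
      hrv_feature_vector(win)
    })
    out$hrv <- dplyr::bind_cols(id_cols(),
                                tibble::as_tibble(do.call(rbind, rows)))
  }

  if (!is.null(bundle$eeg)) {
    fs <- bundle$fs$eeg
    pp <- preprocess_eeg(bundle$eeg, fs, ica = ica, seed = seed)
    rows <- lapply(seq_len(nrow(ads)), function(i) {
      eeg_feature_vectors(pp$eeg, fs, timeline, ads$ad_id[i],
                          sample_mask = pp$sample_mask)
    })
    out$eeg_gfp_zscore <- dplyr::bind_cols(
      id_cols(),
      tibble::as_tibble(do.call(rbind, lapply(rows, `[[`, "gfp_zscore"))))
    out$eeg_psd <- dplyr::bind_cols(
      id_cols(),
      tibble::as_tibble(do.call(rbind, lapply(rows, `[[`, "psd"))))
    out$eeg_ind <- dplyr::bind_cols(
      id_cols(),
      tibble::as_tibble(do.call(rbind, lapply(rows, `[[`, "index"))))
  }
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param ica,seed Passed to [extract_subject_features()].
#' @return Named list of feature tibbles (one row per subject x ad), the
#'   classifier substrate fed to [assemble_variant()].
#' @export
extract_cohort_features <- function(cohort, ica = TRUE, seed = 1L) {
  per_subject <- lapply(cohort$subjects, extract_subject_features,
                        ica = ica, seed = seed)
  families <- unique(unlist(lapply(per_subject, names)))
  out <- lapply(families, function(f) {
    dplyr::bind_rows(lapply(per_subject, function(s) s[[f]]))
  })
  stats::setNames(out, families)
}

#' Simulate a study and extract its features in one pass
#'
#' Streams subject generation and feature extraction (each bundle is
#' discarded once its features are computed), which keeps memory flat for
#' large cohorts.
#'
#' @inheritParams generate_cohort
#' @param ica Run ICA in the EEG chain.
#' @return Named list of feature tibbles as in [extract_cohort_features()].
#' @export
simulate_study <- function(n_subjects,
                           class_effects = class_effects_strong(),
                           seed = 1L, config = session_config(),
                           signals = c("eeg", "ecg", "gsr", "rsp"),
                           drop_model = default_drop_model(),
                           ad_labels = default_ad_labels(config$ad_ids),
                           ica = TRUE, ...) {
  seeds <- derive_seeds(seed + 1L, n_subjects)
  dropped <- cohort_drops(n_subjects, drop_model, seed)
  per_subject <- lapply(seq_len(n_subjects), function(i) {
    # per-subject ad order: presentation sequence must not confound class
    timeline <- generate_timeline(config, seed = seeds[i])
    profile <- subject_profile(sprintf("s%02d", i), timeline,
                               ad_labels = ad_labels,
                               class_effects = class_effects,
                               rng_seed = seeds[i])
    keep <- setdiff(signals, dropped[[i]])
    if (length(keep) == 0) return(NULL)
    bundle <- generate_subject(timeline, profile, signals = keep, ...)
    extract_subject_features(bundle, ica = ica, seed = seeds[i])
  })
  per_subject <- Filter(Negate(is.null), per_subject)
  families <- unique(unlist(lapply(per_subject, names)))
  out <- lapply(families, function(f) {
    dplyr::bind_rows(lapply(per_subject, function(s) s[[f]]))
  })
  stats::setNames(out, families)
}
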