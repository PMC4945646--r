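#' Dataset variants
#'
#' The canonical dataset variants and their constituent feature families,
#' with the expected feature counts: GSR 10, RSP 6, HRV 56, EEG_GFP-ZSCORE
#' 18, EEG_PSD 72, EEG_IND 8, EEG_ALL 98, GSR+HRV 66, GSR+HRV+EEG_IND 74,
#' GSR+HRV+EEG_ALL 164.
#'
#' @return Named list mapping variant name to feature-family names.
#' @export
variant_definitions <- function() {
  list(
    "GSR" = "gsr",
    "RSP" = "rsp",
    "HRV" = "hrv",
    "EEG_GFP-ZSCORE" = "eeg_gfp_zscore",
    "EEG_PSD" = "eeg_psd",
    "EEG_IND" = "eeg_ind",
    "EEG_ALL" = c("eeg_gfp_zscore", "eeg_psd", "eeg_ind"),
    "GSR+HRV" = c("gsr", "hrv"),
    "GSR+HRV+EEG_IND" = c("gsr", "hrv", "eeg_ind"),
    "GSR+HRV+EEG_ALL" = c("gsr", "hrv", "eeg_gfp_zscore", "eeg_psd",
                          "eeg_ind")
  )
}

#' Assemble a dataset variant
#'
#' Joins the per-signal feature tables of a variant on (subject, ad),
#' keeping only instances present in every constituent family (a subject
#' whose ECG was dropped contributes to no HRV-containing variant). Feature
#' columns keep a deterministic order: families in definition order, each
#' family's columns in extraction order.
#'
#' @param variant Variant name, see [variant_definitions()].
#' @param cohort_features Named list of feature tibbles from
#'   [extract_cohort_features()] / [simulate_study()].
#' @return A `feature_table` tibble: `subject`, `ad`, `label`, then the
#'   variant's feature columns; attribute `variant` records the tag.
#' @export
assemble_variant <- function(variant, cohort_features) {
  defs <- variant_definitions()
  assert_that(variant %in% names(defs),
              paste0("unknown variant '", variant, "'"))
  fams <- defs[[variant]]
  missing <- setdiff(fams, names(cohort_features))
  assert_that(length(missing) == 0,
              paste("missing feature families:",
                    paste(missing, collapse = ", ")))
  tabs <- cohort_features[fams]
  out <- tabs[[1]]
  if (length(tabs) > 1) {
    for (t2 in tabs[-1]) {
      out <- dplyr::inner_join(out, dplyr::select(t2, -"label"),
                               by = c("subject", "ad"))
    }
  }
  # drop instances with an entirely missing family block (e.g. tachogram
  # failure), keep sporadic missing metrics for imputation downstream
  assert_that(nrow(out) > 0, "empty instance intersection")
  out <- tibble::as_tibble(out)
  attr(out, "variant") <- variant
  class(out) <- c("feature_table", class(out))
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject", "ad", "label"))
}

#' Split off unlabeled holdout instances
#'
#' @param table A `feature_table`.
#' @return List `labeled` / `holdout`.
#' @export
split_holdout <- function(table) {
  hold <- table$label == "unlabeled" | is.na(table$label)
  list(labeled = table[!hold, , drop = FALSE],
       holdout = table[hold, , drop = FALSE])
}

#' Standardize feature columns
#'
#' Scales every feature column to zero mean and unit variance. Constant
#' columns are set to zero with a warning. Missing entries are mean-imputed
#' (zero after scaling) so downstream learners see complete data; the
#' centers and scales are stored in attributes so holdout instances can be
#' transformed with the training parameters via [apply_standardization()].
#'
#' @param table A `feature_table`.
#' @return The standardized table with attributes `center` and `scale`.
#' @export
standardize_features <- function(table) {
  cols <- feature_columns(table)
  center <- vapply(cols, function(c) mean(table[[c]], na.rm = TRUE),
                   numeric(1))
  scale <- vapply(cols, function(c) stats::sd(table[[c]][
    !is.na(table[[c]])]), numeric(1))
  const <- !is.finite(scale) | scale == 0
  if (any(const)) {
    warning("constant feature column(s) set to 0: ",
            paste(cols[const], collapse = ", "))
    scale[const] <- 1
    center[const] <- vapply(cols[const], function(c) {
      v <- table[[c]][!is.na(table[[c]])]
      if (length(v) == 0) 0 else v[1]
    }, numeric(1))
  }
  center[!is.finite(center)] <- 0
  for (i in seq_along(cols)) {
    v <- (table[[cols[i]]] - center[i]) / scale[i]
    v[!is.finite(v)] <- 0
    table[[cols[i]]] <- v
  }
  attr(table, "center") <- center
  attr(table, "scale") <- scale
  table
}

#' Apply stored standardization parameters to new instances
#'
#' @param table New instances (same feature columns).
#' @param trained A table returned by [standardize_features()] (or a list
#'   with `center`/`scale`).
#' @return Standardized table.
#' @export
apply_standardization <- function(table, trained) {
  center <- attr(trained, "center") %||% trained$center
  scale <- attr(trained, "scale") %||% trained$scale
  for (c in names(center)) {
    v <- (table[[c]] - center[[c]]) / scale[[c]]
    v[!is.finite(v)] <- 0
    table[[c]] <- v
  }
  table
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling: each synthetic instance is a uniform
#' convex combination of a real minority instance and one of its `k`
#' same-class nearest neighbours (Euclidean distance over the feature
#' columns, missing values mean-imputed for the distance computation).
#' Minority classes are oversampled until every class matches the majority
#' count. An already-balanced table is returned unchanged.
#'
#' @param table A `feature_table` with a `label` column.
#' @param k Number of nearest neighbours (default 5); reduced with a
#'   warning when a class has fewer than `k + 1` members.
#' @param seed Seed for neighbour and interpolation draws.
#' @return Balanced table; synthetic rows carry `synthetic_` subject ids.
#' @export
smote_balance <- function(table, k = 5, seed = 1L) {
  cols <- feature_columns(table)
  counts <- table(table$label)
  target <- max(counts)
  if (all(counts == target)) return(table)
  x_all <- as.matrix(table[, cols])
  # mean-impute for distance computation only
  for (j in seq_len(ncol(x_all))) {
    bad <- !is.finite(x_all[, j])
    if (any(bad)) x_all[bad, j] <- mean(x_all[!bad, j])
  }
  new_rows <- list()
  with_local_seed(seed, {
    for (cls in names(counts)[counts < target]) {
      idx <- which(table$label == cls)
      kk <- k
      if (length(idx) < k + 1) {
        kk <- max(1L, length(idx) - 1L)
        warning(sprintf("class '%s' has %d members; k reduced to %d",
                        cls, length(idx), kk))
      }
      x <- x_all[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(x))
      diag(d) <- Inf
      need <- target - length(idx)
      base <- idx[1 + (seq_len(need) - 1L) %% length(idx)]
      for (s in seq_len(need)) {
        i_local <- match(base[s], idx)
        nb_local <- order(d[i_local, ])[sample.int(kk, 1)]
        u <- stats::runif(1)
        synth <- x[i_local, ] + u * (x[nb_local, ] - x[i_local, ])
        row <- table[idx[i_local], , drop = FALSE]
        row[cols] <- as.list(synth)
        row$subject <- paste0("synthetic_", cls, "_", s)
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
  })
  out <- dplyr::bind_rows(c(list(table), new_rows))
  attr(out, "variant") <- attr(table, "variant")
  class(out) <- unique(c("feature_table", class(out)))
  out
}

#' Stratified fold assignment
#'
#' Assigns each instance to one of `k` folds so that every class is spread
#' as evenly as possible: class proportions per fold deviate from the global
#' proportions by at most one instance.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffles.
#' @return Integer fold id per instance.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(sample(k), length(idx))
    }
  })
  folds
}
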