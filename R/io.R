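#' Write a signal bundle to disk
#'
#' One CSV per signal (`time_s` plus one column per channel) and a JSON
#' sidecar describing the timeline and sampling rates.
#'
#' @param bundle A `signal_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_signal_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sig in c("eeg", "ecg", "gsr", "rsp")) {
    x <- bundle[[sig]]
    if (is.null(x)) next
    fs <- bundle$fs[[sig]]
    if (is.matrix(x)) {
      df <- data.frame(time_s = seq_len(ncol(x)) / fs, t(x),
                       check.names = FALSE)
    } else {
      df <- data.frame(time_s = seq_along(x) / fs, value = x)
    }
    utils::write.csv(df, file.path(dir, paste0(sig, ".csv")),
                     row.names = FALSE)
  }
  tl <- bundle$timeline
  side <- list(
    subject_id = bundle$profile$subject_id,
    total_duration = tl$total_duration,
    ad_order_seed = tl$ad_order_seed,
    fs = bundle$fs[!vapply(bundle[c("eeg", "ecg", "gsr", "rsp")], is.null,
                           logical(1))],
    blocks = tl$blocks |>
      dplyr::mutate(brand_windows = lapply(.data$brand_windows, function(b) {
        if (is.null(b)) list() else b
      }))
  )
  jsonlite::write_json(side, file.path(dir, "timeline.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  invisible(dir)
}

#' Read a signal bundle written by [write_signal_bundle()]
#'
#' @param dir Directory holding the CSVs and `timeline.json`.
#' @return A list with the signal vectors/matrices, sampling rates and the
#'   timeline metadata (not a full `signal_bundle`: profile and ground-truth
#'   ledger are generation-time objects and are not serialized).
#' @export
read_signal_bundle <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "timeline.json"),
                              simplifyVector = TRUE)
  out <- list(fs = as.list(side$fs), timeline_meta = side)
  for (sig in c("eeg", "ecg", "gsr", "rsp")) {
    f <- file.path(dir, paste0(sig, ".csv"))
    if (!file.exists(f)) next
    df <- utils::read.csv(f, check.names = FALSE)
    if (ncol(df) == 2 && identical(names(df)[2], "value")) {
      out[[sig]] <- df$value
    } else {
      m <- t(as.matrix(df[, -1, drop = FALSE]))
      out[[sig]] <- m
    }
  }
  out
}

#' Write a feature table as CSV
#'
#' @param table A feature tibble (e.g. from [assemble_variant()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV written by [write_feature_csv()].
#' @return Tibble with `label` as character.
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' Write a feature table as ARFF
#'
#' The Weka dialect: numeric attributes followed by a nominal class
#' attribute (`label`) last. Identifier columns are stored as strings.
#'
#' @param table Feature tibble with a `label` column.
#' @param path Output `.arff` file.
#' @return `path`, invisibly.
#' @export
write_feature_arff <- function(table, path) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("package 'foreign' is required for ARFF export", call. = FALSE)
  }
  df <- as.data.frame(table)
  stopifnot("label" %in% names(df))
  df <- df[, c(setdiff(names(df), "label"), "label")]
  df$label <- factor(df$label)
  foreign::write.arff(df, path)
  invisible(path)
}

#' Read an ARFF feature table
#'
#' @param path `.arff` file.
#' @return Tibble with `label` as character.
#' @export
read_feature_arff <- function(path) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("package 'foreign' is required for ARFF import", call. = FALSE)
  }
  df <- foreign::read.arff(path)
  if ("label" %in% names(df)) df$label <- as.character(df$label)
  tibble::as_tibble(df)
}
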