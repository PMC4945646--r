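#' Session design configuration
#'
#' Describes the layout of one viewing session: a documentary interrupted by
#' three blocks of commercials, three ads per block. The first ad block may
#' not start before minute 7 and every ad block must be preceded by at least
#' two minutes of documentary, which later serves as the EEG baseline window.
#'
#' @param doc_lengths Numeric vector of four documentary segment lengths in
#'   seconds: before block 1, between blocks 1-2, between blocks 2-3, and
#'   after block 3 (the last may be 0). The default places block 1 at
#'   7 minutes, block 2 at mid-session and block 3 at the session end of a
#'   30-minute trial.
#' @param ad_duration Ad length in seconds (default 30, a typical spot).
#' @param ads_per_block Number of ads per block; the session design fixes 3.
#' @param ad_ids Character identifiers of the nine ads shown.
#' @param brand_windows List of two-element numeric vectors, brand-exposure
#'   intervals in seconds relative to each ad's onset (`[start, end)`).
#'
#' @return A list of class `session_config`.
#' @export
session_config <- function(doc_lengths = c(420, 345, 765, 0),
                           ad_duration = 30,
                           ads_per_block = 3,
                           ad_ids = sprintf("ad%02d", 1:9),
                           brand_windows = list(c(12, 15), c(25, 30))) {
  assert_that(length(doc_lengths) == 4 && all(doc_lengths >= 0),
              "`doc_lengths` must be four non-negative segment lengths")
  assert_that(ad_duration > 0, "`ad_duration` must be positive")
  assert_that(ads_per_block == 3, "the session design uses 3 ads per block")
  assert_that(length(ad_ids) == 3 * ads_per_block && !anyDuplicated(ad_ids),
              "`ad_ids` must hold 9 distinct identifiers")
  ok <- vapply(brand_windows, function(w) {
    length(w) == 2 && w[1] >= 0 && w[2] <= ad_duration && w[1] < w[2]
  }, logical(1))
  assert_that(all(ok), "brand windows must lie within [0, ad_duration)")
  structure(
    list(doc_lengths = doc_lengths, ad_duration = ad_duration,
         ads_per_block = ads_per_block, ad_ids = ad_ids,
         brand_windows = brand_windows),
    class = "session_config"
  )
}

#' Generate a session timeline
#'
#' Lays out documentary and ad blocks and assigns the nine ads to the three
#' blocks by a seeded permutation, so that presentation order cannot act as a
#' confound. The resulting timeline is shared by all signals of a subject.
#'
#' @param config A [session_config()].
#' @param seed Integer seed controlling the ad-order permutation.
#'
#' @return A `session_timeline`: list with `total_duration` (s), `blocks`
#'   (a tibble with one row per stimulus block: `kind`, `block` index for ad
#'   rows, `onset`, `duration`, `ad_id`, and a `brand_windows` list-column of
#'   absolute `[start, end)` intervals) and `ad_order_seed`.
#' @export
#' @examples
#' tl <- generate_timeline(session_config(), seed = 1)
#' ad_blocks(tl)
generate_timeline <- function(config = session_config(), seed = 1L) {
  n_blocks <- 3L
  block_len <- config$ads_per_block * config$ad_duration
  onsets <- cumsum(c(config$doc_lengths[1],
                     block_len + config$doc_lengths[2],
                     block_len + config$doc_lengths[3]))
  assert_that(onsets[1] >= 420,
              "first ad block must start at least 7 min into the session")
  assert_that(all(config$doc_lengths[1:3] >= 120),
              "every ad block needs >= 2 min of preceding documentary baseline")
  total <- onsets[3] + block_len + config$doc_lengths[4]

  order <- with_local_seed(seed, sample(config$ad_ids))

  rows <- list()
  t0 <- 0
  k <- 0L
  for (b in seq_len(n_blocks)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = "documentary", block = NA_integer_, onset = t0,
      duration = onsets[b] - t0, ad_id = NA_character_,
      brand_windows = list(NULL))
    t0 <- onsets[b]
    for (a in seq_len(config$ads_per_block)) {
      k <- k + 1L
      bw <- lapply(config$brand_windows, function(w) w + t0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "ad", block = b, onset = t0, duration = config$ad_duration,
        ad_id = order[k], brand_windows = list(bw))
      t0 <- t0 + config$ad_duration
    }
  }
  if (config$doc_lengths[4] > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = "documentary", block = NA_integer_, onset = t0,
      duration = config$doc_lengths[4], ad_id = NA_character_,
      brand_windows = list(NULL))
  }
  blocks <- dplyr::bind_rows(rows)

  structure(
    list(total_duration = total, blocks = blocks, ad_order_seed = seed,
         config = config),
    class = "session_timeline"
  )
}

#' Ad blocks of a timeline
#'
#' @param timeline A `session_timeline`.
#' @return Tibble of the nine ad rows (block, onset, duration, ad_id,
#'   brand_windows).
#' @export
ad_blocks <- function(timeline) {
  dplyr::filter(timeline$blocks, .data$kind == "ad")
}

#' Baseline window preceding an ad block
#'
#' The two minutes of documentary immediately before the block containing an
#' ad serve as the neutral reference against which stimulus-period global
#' field power is standardized.
#'
#' @param timeline A `session_timeline`.
#' @param block Ad block index (1-3).
#' @return Numeric `c(start, end)` in seconds, a 120-s interval.
#' @export
baseline_window <- function(timeline, block) {
  ads <- ad_blocks(timeline)
  onset <- min(ads$onset[ads$block == block])
  c(onset - 120, onset)
}

#' @export
print.session_timeline <- function(x, ...) {
  ads <- ad_blocks(x)
  cat(sprintf("<session_timeline> %.0f s, %d ad blocks (%d ads), seed %d\n",
              x$total_duration, max(ads$block), nrow(ads), x$ad_order_seed))
  print(x$blocks, n = nrow(x$blocks))
  invisible(x)
}
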