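#' Detect alternating extrema
#'
#' Scans the first differences of a (morphologically smoothed) signal for
#' sign changes. Plateaus are resolved to their midpoint; strict alternation
#' of minima and maxima is enforced by merging the lesser of two same-type
#' neighbours. A constant signal has no extrema. Segment boundaries are
#' included when they are local minima (so an isolated pulse has flanking
#' minima), but never as maxima: a peak must be witnessed by a fall on both
#' sides, which keeps event counts free of segment-edge artifacts.
#'
#' @param x Smoothed numeric signal.
#' @param fs Sampling rate (Hz) used to express extremum times.
#' @param min_prominence Minimum rise/fall between adjacent extrema; pairs
#'   closer in amplitude are merged away (0 = keep every sign change).
#'   Feature extractors set this just above the instrument-noise floor so
#'   residual ripple that survives the morphological filter is not counted
#'   as events.
#' @return An `extrema` tibble: `time` (s), `value`, `type`
#'   (`"min"`/`"max"`), strictly alternating and increasing in time.
#' @export
detect_extrema <- function(x, fs = 32, min_prominence = 0) {
  n <- length(x)
  if (n < 3) {
    return(empty_extrema())
  }
  # compress plateaus (runs of equal value) to their midpoints
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- floor((starts + ends) / 2)
  v <- r$values
  m <- length(v)
  if (m < 3) {
    return(empty_extrema())
  }
  d <- sign(diff(v))
  turn <- which(d[-1] != d[-(m - 1)]) + 1L
  type <- ifelse(d[turn] > 0, "min", "max")
  idx <- turn
  if (d[1] > 0) { # rising from the boundary: leading minimum
    idx <- c(1L, idx)
    type <- c("min", type)
  }
  if (d[m - 1] < 0) { # falling into the boundary: trailing minimum
    idx <- c(idx, m)
    type <- c(type, "min")
  }
  if (length(idx) == 0) {
    return(empty_extrema())
  }
  out <- tibble::tibble(time = mids[idx] / fs, value = v[idx], type = type)
  # enforce alternation: merge the lesser of two same-type neighbours
  repeat {
    same <- which(out$type[-1] == out$type[-nrow(out)])
    if (length(same) == 0) break
    i <- same[1]
    pair <- out[c(i, i + 1L), ]
    drop <- if (pair$type[1] == "max") {
      c(i, i + 1L)[which.min(pair$value)]
    } else {
      c(i, i + 1L)[which.max(pair$value)]
    }
    out <- out[-drop, ]
  }
  # merge low-prominence neighbour pairs (alternation is preserved because
  # removing an adjacent max/min pair leaves opposite types adjacent)
  while (min_prominence > 0 && nrow(out) >= 2) {
    dv <- abs(diff(out$value))
    i <- which.min(dv)
    if (dv[i] >= min_prominence) break
    out <- out[-c(i, i + 1L), ]
  }
  class(out) <- c("extrema", class(out))
  out
}

empty_extrema <- function() {
  out <- tibble::tibble(time = numeric(), value = numeric(),
                        type = character())
  class(out) <- c("extrema", class(out))
  out
}

#' Skin conductance features for one stimulus
#'
#' Ten statistics of a smoothed GSR segment: mean, variance and SD of the
#' conductance; the numbers of local maxima and minima; the mean rise
#' (`G_F - G_B`) over consecutive minimum-to-maximum pairs (each maximum
#' paired with the immediately preceding minimum); the global maximum,
#' minimum and their difference; and the peak rate (maxima per second).
#'
#' @param gsr Smoothed conductance segment (microsiemens).
#' @param fs Sampling rate (Hz).
#' @param min_prominence Event amplitude floor in microsiemens (default
#'   0.02, well below typical sudomotor responses).
#' @return Named numeric vector of length 10 (`gsr_` prefix).
#' @export
gsr_features <- function(gsr, fs = 32, min_prominence = 0.02) {
  assert_that(length(gsr) >= 2, "empty GSR segment")
  duration <- length(gsr) / fs
  ex <- detect_extrema(gsr, fs, min_prominence = min_prominence)
  maxima <- ex[ex$type == "max", ]
  minima <- ex[ex$type == "min", ]
  rises <- numeric()
  for (i in seq_len(nrow(maxima))) {
    prev_min <- minima[minima$time < maxima$time[i], ]
    if (nrow(prev_min) > 0) {
      rises <- c(rises, maxima$value[i] - prev_min$value[nrow(prev_min)])
    }
  }
  c(gsr_mean = mean(gsr),
    gsr_variance = stats::var(gsr),
    gsr_sd = stats::sd(gsr),
    gsr_n_maxima = nrow(maxima),
    gsr_n_minima = nrow(minima),
    gsr_mean_rise = if (length(rises) > 0) mean(rises) else NA_real_,
    gsr_max = max(gsr),
    gsr_min = min(gsr),
    gsr_range = max(gsr) - min(gsr),
    gsr_peaks_per_time = nrow(maxima) / duration)
}

#' Respiration features for one stimulus
#'
#' Six statistics of a smoothed respiration segment: respiratory rate
#' (breaths/min, counting inhalation maxima), mean level, longest and
#' shortest interval between consecutive breaths (max-to-max, seconds), and
#' the deepest (`rsp_max`) and shallowest (`rsp_min`) excursions.
#'
#' @param rsp Smoothed respiration segment.
#' @param fs Sampling rate (Hz).
#' @param min_prominence Breath amplitude floor (default 0.1 of the
#'   signal's arbitrary units).
#' @return Named numeric vector of length 6 (`rsp_` prefix); interval
#'   entries are missing when fewer than two breaths are detected.
#' @export
rsp_features <- function(rsp, fs = 32, min_prominence = 0.1) {
  assert_that(length(rsp) >= 2, "empty RSP segment")
  duration <- length(rsp) / fs
  ex <- detect_extrema(rsp, fs, min_prominence = min_prominence)
  breaths <- ex$time[ex$type == "max"]
  ibi <- if (length(breaths) >= 2) diff(breaths) else numeric()
  c(rsp_rate = length(breaths) * 60 / duration,
    rsp_mean = mean(rsp),
    rsp_ibi_longest = if (length(ibi) > 0) max(ibi) else NA_real_,
    rsp_ibi_shortest = if (length(ibi) > 0) min(ibi) else NA_real_,
    rsp_max = max(rsp),
    rsp_min = min(rsp))
}
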