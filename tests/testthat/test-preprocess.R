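test_that("kurtosis matches its defining moments", {
  expect_equal(kurtosis_coef(rep(c(-1, 1), 50)), 1)
  expect_true(is.na(kurtosis_coef(rep(3, 100))))
  x <- withr::with_seed(1, rnorm(1e5))
  expect_lt(abs(kurtosis_coef(x) - 3), 0.1)
  # brute-force check on an arbitrary vector
  y <- withr::with_seed(2, rexp(500))
  mu <- mean(y)
  expect_equal(kurtosis_coef(y),
               mean((y - mu)^4) / mean((y - mu)^2)^2)
})

test_that("flat and spiky channels are rejected, healthy montages are not", {
  nch <- 30
  n <- 30 * 256
  mk <- function(seed) {
    m <- withr::with_seed(seed, matrix(rnorm(nch * n), nch, n))
    rownames(m) <- electrode_positions()$channel
    m
  }
  clean <- mk(1)
  expect_false(any(detect_bad_channels(clean)$rejected))

  flat <- mk(2)
  flat["C3", 1:round(0.15 * n)] <- flat["C3", 1]
  rep_flat <- detect_bad_channels(flat)
  expect_true(rep_flat$rejected[rep_flat$channel == "C3"])
  expect_gt(rep_flat$flat_fraction[rep_flat$channel == "C3"], 0.10)

  spiky <- mk(3)
  at <- withr::with_seed(4, sample.int(n, 40))
  spiky["P4", at] <- spiky["P4", at] + 30
  rep_spiky <- detect_bad_channels(spiky)
  expect_true(rep_spiky$rejected[rep_spiky$channel == "P4"])
  # reported kurtosis equals a per-channel recomputation
  expect_equal(rep_spiky$kurtosis,
               apply(spiky, 1, kurtosis_coef), ignore_attr = TRUE)
})

test_that("QC + interpolation is idempotent and respects neighbours", {
  nch <- 30
  n <- 10 * 256
  m <- withr::with_seed(5, matrix(rnorm(nch * n), nch, n))
  rownames(m) <- electrode_positions()$channel
  # no rejections: identity
  rep0 <- detect_bad_channels(m)
  expect_identical(interpolate_channels(m, rep0), m)
  # rejected channel amid identical neighbours equals that signal
  shared <- withr::with_seed(6, rnorm(n))
  m2 <- m
  for (ch in c("F3", "Fc5", "Fc1", "F7", "Fp1", "Fz")) m2[ch, ] <- shared
  qc <- tibble::tibble(channel = rownames(m2),
                      rejected = rownames(m2) == "F3")
  out <- interpolate_channels(m2, qc)
  expect_equal(out["F3", ], shared, tolerance = 1e-12)
  # linear spatial gradient: interpolation error well below the gradient
  pos <- electrode_positions()
  grad <- matrix(rep(pos$x * 10, n), nch, n)
  rownames(grad) <- pos$channel
  qc2 <- tibble::tibble(channel = pos$channel,
                        rejected = pos$channel == "C3")
  out2 <- interpolate_channels(grad, qc2)
  spacing_effect <- 10 * 0.5 # neighbour spacing in the gradient's units
  expect_lt(max(abs(out2["C3", ] - grad["C3", ])), spacing_effect)
  # running detect -> interpolate twice changes nothing the second time
  b <- eeg_bundle()$eeg[, 1:(20 * 256)]
  f <- filter_eeg(b, 256)
  r1 <- detect_bad_channels(f)
  i1 <- interpolate_channels(f, r1)
  r2 <- detect_bad_channels(i1)
  i2 <- interpolate_channels(i1, r2)
  expect_equal(i1, i2, tolerance = 1e-9)
})

test_that("the EEG band-pass removes DC, keeps 10 Hz and rejects 60 Hz", {
  fs <- 256
  t <- seq_len(20 * fs) / fs
  dc <- matrix(5, 2, length(t))
  rownames(dc) <- c("Fp1", "Fp2")
  expect_lt(max(abs(rowMeans(filter_eeg(dc, fs)))), 1e-6)
  probe <- function(freq) {
    x <- matrix(sin(2 * pi * freq * t), 1, length(t))
    rownames(x) <- "Cz"
    y <- filter_eeg(x, fs)
    mid <- (5 * fs):(15 * fs)
    sd(y[1, mid]) / sd(x[1, mid])
  }
  expect_lt(abs(probe(10) - 1), 0.05)
  expect_lt(20 * log10(probe(60)), -20)
})

test_that("epoching keeps clean seconds and drops spiky ones", {
  fs <- 256
  m <- withr::with_seed(7, matrix(rnorm(4 * 10 * fs), 4, 10 * fs))
  rownames(m) <- c("Fp1", "Fp2", "F3", "F4")
  ep <- epoch_and_reject(m, fs)
  expect_equal(dim(ep$data), c(10, 4, fs))
  expect_true(all(ep$keep))
  m2 <- m
  m2[2, 3 * fs + 10] <- 60 # massive spike inside epoch 4
  ep2 <- epoch_and_reject(m2, fs)
  expect_false(ep2$keep[4])
  expect_true(all(ep2$keep[-4]))
  expect_false(any(ep2$sample_mask[(3 * fs + 1):(4 * fs)]))
})

test_that("ICA flags blink components and leaves clean data alone", {
  pp <- eeg_preprocessed()
  dec <- pp$decomposition
  expect_gte(length(dec$rejected), 1)
  raw_filtered <- filter_eeg(eeg_bundle()$eeg, 256)
  drop <- 1 - var(pp$eeg["Fp1", ]) / var(raw_filtered["Fp1", ])
  expect_gte(drop, 0.5)
  # mixing o unmixing reproduces the data it was fitted to (identity on
  # the retained subspace; interpolation leaves the montage rank-deficient)
  p <- dec$mixing %*% dec$unmixing
  probe <- pp$eeg[, 1000:1200] - rowMeans(pp$eeg)
  recon <- p %*% probe
  expect_lt(max(abs(recon - probe)) / max(abs(probe)), 1e-4)
  # blink-free recording: nothing rejected, output untouched
  tl <- small_timeline()
  clean <- generate_subject(
    tl, subject_profile("c", tl, rng_seed = 31), signals = "eeg",
    eeg_args = list(blink_rate = 0))
  xf <- filter_eeg(clean$eeg[, 1:(120 * 256)], 256)
  res <- reject_artifact_components(xf, 256, seed = 5)
  expect_length(res$decomposition$rejected, 0)
  expect_identical(res$eeg, xf)
})

test_that("epoch rejection rate on clean synthetic EEG stays under 5%", {
  tl <- small_timeline()
  clean <- generate_subject(
    tl, subject_profile("c2", tl, rng_seed = 33), signals = "eeg",
    eeg_args = list(blink_rate = 0))
  ep <- epoch_and_reject(filter_eeg(clean$eeg[, 1:(300 * 256)], 256), 256)
  expect_lt(mean(!ep$keep), 0.05)
})

test_that("ECG filters hit their stopbands and preserve the QRS", {
  fs <- 256
  t <- seq_len(60 * fs) / fs
  atten <- function(freq) {
    x <- sin(2 * pi * freq * t)
    y <- preprocess_ecg(x, fs)
    mid <- (20 * fs):(40 * fs)
    20 * log10(sd(y[mid]) / sd(x[mid]))
  }
  expect_lt(atten(0.1), -20)
  expect_lt(atten(50), -20)
  ecg <- template_ecg(60, duration_s = 60, noise_sd = 0)
  y <- preprocess_ecg(ecg, fs)
  r_idx <- round(seq(1, 59, by = 1) * fs)
  # compare against the mean-subtracted input: DC removal is part of the
  # contract, the QRS morphology on top of it must survive intact
  x0 <- ecg - mean(ecg)
  before <- vapply(r_idx, function(i) max(x0[(i - 20):(i + 20)]),
                   numeric(1))
  after <- vapply(r_idx, function(i) max(y[(i - 20):(i + 20)]), numeric(1))
  expect_lt(max(abs(after - before) / before), 0.05)
})

test_that("filters are zero-phase in effect", {
  fs <- 256
  x <- numeric(30 * fs)
  x[seq(5 * fs, 25 * fs, by = 2 * fs)] <- 1 # sparse pulses
  x <- as.numeric(stats::filter(x, rep(1 / 10, 10), sides = 2))
  x[is.na(x)] <- 0
  y <- preprocess_ecg(x, fs)
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  m <- matrix(x, 2, length(x), byrow = TRUE)
  rownames(m) <- c("Cz", "Pz")
  ye <- filter_eeg(m, fs)
  cc2 <- stats::ccf(ye[1, ], x, lag.max = 20, plot = FALSE)
  expect_equal(cc2$lag[which.max(cc2$acf)], 0)
})

test_that("morphological filter removes ripple and keeps structure", {
  # monotone input passes unchanged away from the element-width boundary
  ramp <- seq(0, 1, length.out = 200)
  sm_ramp <- morphological_filter(ramp, 0.5, 32)
  expect_equal(sm_ramp[18:183], ramp[18:183])
  expect_true(all(diff(sm_ramp) >= 0))
  plateau <- c(rep(0, 50), rep(1, 50), rep(0, 50))
  rippled <- plateau
  rippled[75] <- 1.5 # single-sample ripple on the plateau
  sm <- morphological_filter(rippled, 0.25, 32)
  # brute-force opening/closing oracle with the same element
  w <- 9
  ero <- function(x) vapply(seq_along(x), function(i) {
    min(x[max(1, i - 4):min(length(x), i + 4)])
  }, numeric(1))
  dil <- function(x) vapply(seq_along(x), function(i) {
    max(x[max(1, i - 4):min(length(x), i + 4)])
  }, numeric(1))
  expect_equal(max(sm), 1)
  expect_lt(max(abs(sm[10:140] - ero(dil(dil(ero(rippled))))[10:140])),
            1e-12)
  # SCR-bearing trace: local maxima equal the injected event count
  tl <- small_timeline()
  ads <- ad_blocks(tl)
  g <- autonomic_bundle()
  smg <- morphological_filter(g$gsr, 0.5, 32)
  scr <- g$ledger$scr_times
  # count events over the whole session, merging pairs closer than 3 s
  sep <- scr[c(TRUE, diff(scr) > 3)]
  ex <- detect_extrema(smg, 32, min_prominence = 0.02)
  n_max <- sum(ex$type == "max")
  expect_lt(abs(n_max - length(sep)) / length(sep), 0.15)
})
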