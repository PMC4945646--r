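test_that("Pan-Tompkins finds template beats and ignores degenerate input", {
  ecg <- template_ecg(60, duration_s = 60)
  pk <- detect_r_peaks(ecg, 256)
  expect_lte(abs(length(pk$index) - 59), 1) # beats at 1..59 s
  truth <- seq(1, 59, by = 1)
  d <- vapply(truth, function(t) min(abs(pk$time - t)), numeric(1))
  expect_lt(max(d), 0.02)
  expect_length(detect_r_peaks(rep(0, 10 * 256), 256)$index, 0)
  # adaptive thresholds make detection amplitude-invariant
  pk2 <- detect_r_peaks(2 * ecg, 256)
  expect_identical(pk$index, pk2$index)
  # refractory: gaps never below 200 ms
  expect_true(all(diff(pk$index) >= 0.2 * 256))
})

test_that("R-peak sensitivity and predictivity reach 99% from 40-120 bpm", {
  for (bpm in c(40, 60, 90, 120)) {
    ecg <- template_ecg(bpm, duration_s = 120, seed = bpm)
    pk <- detect_r_peaks(ecg, 256)
    truth <- seq(1, 119, by = 60 / bpm)
    sens <- mean(vapply(truth, function(t) min(abs(pk$time - t)) < 0.05,
                        logical(1)))
    ppv <- mean(vapply(pk$time, function(t) min(abs(truth - t)) < 0.05,
                       logical(1)))
    expect_gte(sens, 0.99)
    expect_gte(ppv, 0.99)
  }
})

test_that("the tachogram artifact rule removes ectopic-like intervals", {
  peaks <- structure(list(index = seq(0, 60, by = 1) * 256 + 1,
                          time = seq(0, 60, by = 1), fs = 256),
                     class = "r_peaks")
  tac <- build_tachogram(peaks)
  expect_true(all(tac$rr_ms == 1000))
  expect_true(all(tac$kept))
  expect_true(all(diff(tac$time) > 0))
  # a spurious extra peak splits one interval into two short halves
  t2 <- sort(c(seq(0, 60, by = 1), 30.5))
  peaks2 <- structure(list(index = round(t2 * 256) + 1, time = t2,
                           fs = 256), class = "r_peaks")
  tac2 <- build_tachogram(peaks2)
  bad <- which(tac2$rr_ms < 600)
  expect_length(bad, 2)
  expect_false(any(tac2$kept[bad]))
  expect_true(all(tac2$kept[-bad]))
})

test_that("time-domain metrics match a direct-formula oracle", {
  # constant series
  tac <- tibble::tibble(time = cumsum(rep(0.8, 40)), rr_ms = 800,
                        kept = TRUE)
  f <- hrv_time_features(tac)
  expect_equal(f[["t_SDRR"]], 0)
  expect_equal(f[["t_RMSSD"]], 0)
  expect_equal(f[["t_RR50"]], 0)
  expect_equal(f[["t_meanHR"]], 75)
  # alternating 800/860: closed forms
  rr <- rep(c(800, 860), 30)
  tac2 <- tibble::tibble(time = cumsum(rr) / 1000, rr_ms = rr, kept = TRUE)
  f2 <- hrv_time_features(tac2)
  expect_equal(f2[["t_RMSSD"]], 60)
  expect_equal(f2[["t_pRR50"]], 1)
  # random series against naive formulas at 1e-9 relative error
  for (s in 1:5) {
    rr <- withr::with_seed(s, runif(100, 700, 1100))
    tacr <- tibble::tibble(time = cumsum(rr) / 1000, rr_ms = rr,
                           kept = TRUE)
    fr <- hrv_time_features(tacr)
    d <- diff(rr)
    oracle <- c(max(rr), min(rr), mean(rr), median(rr), sd(rr),
                sqrt(mean(d^2)), sum(abs(d) > 50),
                sum(abs(d) > 50) / (length(rr) - 1),
                mean(60000 / rr), sd(60000 / rr))
    got <- fr[c("t_maxRR", "t_minRR", "t_meanRR", "t_medianRR", "t_SDRR",
                "t_RMSSD", "t_RR50", "t_pRR50", "t_meanHR", "t_sdHR")]
    expect_equal(unname(got), oracle, tolerance = 1e-9)
    expect_true(fr[["t_maxRR"]] >= fr[["t_medianRR"]] &&
                fr[["t_medianRR"]] >= fr[["t_minRR"]])
  }
})

test_that("spectral metrics localize the modulation band", {
  # RR modulated at 0.1 Hz only -> LF dominates, peak at 0.1
  t <- cumsum(rep(0.8, 400))
  rr_lf <- 800 + 50 * sin(2 * pi * 0.1 * t)
  tac_lf <- tibble::tibble(time = t, rr_ms = rr_lf, kept = TRUE)
  for (method in c("welch", "lomb")) {
    f <- hrv_spectral_features(tac_lf, method)
    pre <- if (method == "welch") "fw_" else "fl_"
    expect_gt(f[[paste0(pre, "LFHF")]], 1)
    expect_lt(abs(f[[paste0(pre, "peakLF")]] - 0.1), 0.02)
    expect_equal(f[[paste0(pre, "nLF")]] + f[[paste0(pre, "nHF")]], 1,
                 tolerance = 1e-9)
  }
  # 0.25 Hz modulation -> HF dominates
  rr_hf <- 800 + 50 * sin(2 * pi * 0.25 * t)
  tac_hf <- tibble::tibble(time = t, rr_ms = rr_hf, kept = TRUE)
  f2 <- hrv_spectral_features(tac_hf, "welch")
  expect_gt(f2[["fw_pHF"]], f2[["fw_pLF"]])
})

test_that("time-frequency metrics reduce to the global spectrum", {
  t <- cumsum(rep(0.8, 36)) # ~29 s: a single window
  rr <- 800 + 40 * sin(2 * pi * 0.1 * t)
  tac <- tibble::tibble(time = t, rr_ms = rr, kept = TRUE)
  tf <- hrv_time_frequency_features(tac)
  fw <- hrv_spectral_features(tac, "welch")
  expect_equal(unname(tf), unname(fw), tolerance = 1e-12)
  # stationary long tachogram: windowed average close to global
  t2 <- cumsum(rep(0.8, 500))
  rr2 <- 800 + 40 * sin(2 * pi * 0.1 * t2) + 20 * sin(2 * pi * 0.25 * t2)
  tac2 <- tibble::tibble(time = t2, rr_ms = rr2, kept = TRUE)
  tf2 <- hrv_time_frequency_features(tac2)
  fw2 <- hrv_spectral_features(tac2, "welch")
  expect_lt(abs(tf2[["tf_nLF"]] - fw2[["fw_nLF"]]) / fw2[["fw_nLF"]], 0.1)
})

test_that("Poincare axes and sample entropy follow their definitions", {
  rr_const <- tibble::tibble(time = cumsum(rep(0.8, 60)), rr_ms = 800,
                             kept = TRUE)
  nl <- hrv_nonlinear_features(rr_const)
  expect_equal(nl[["nl_SampEn"]], 0)
  expect_equal(nl[["nl_SD1"]], 0)
  # alternating +-60 ms differences: SD1 = 60 / sqrt(2)
  rr_alt <- rep(c(800, 860), 50)
  tac_alt <- tibble::tibble(time = cumsum(rr_alt) / 1000, rr_ms = rr_alt,
                            kept = TRUE)
  nl2 <- hrv_nonlinear_features(tac_alt)
  expect_equal(nl2[["nl_SD1"]], 60 / sqrt(2), tolerance = 0.02)
  # eigen-decomposition oracle on a random tachogram
  rr <- withr::with_seed(9, 800 + cumsum(rnorm(300, 0, 12)))
  tacr <- tibble::tibble(time = cumsum(rr) / 1000, rr_ms = rr, kept = TRUE)
  nlr <- hrv_nonlinear_features(tacr)
  pairs <- cbind(rr[-length(rr)], rr[-1])
  ev <- eigen(stats::cov(pairs))$values
  expect_equal(nlr[["nl_SD1"]], sqrt(min(ev)), tolerance = 0.05)
  expect_equal(nlr[["nl_SD2"]], sqrt(max(ev)), tolerance = 0.05)
})

test_that("the HRV battery always yields 56 stably named metrics", {
  b <- autonomic_bundle()
  clean <- preprocess_ecg(b$ecg, 256)
  tac <- build_tachogram(detect_r_peaks(clean, 256))
  v <- hrv_feature_vector(tac)
  expect_length(v, 56)
  expect_equal(anyDuplicated(names(v)), 0L)
  expect_identical(names(v), names(hrv_feature_vector(tac)))
  # a 30-s ad window still yields all 56 names, with missing entries kept
  ads <- ad_blocks(b$timeline)
  win <- physioad:::tacho_window(tac, ads$onset[1], ads$onset[1] + 30)
  v2 <- hrv_feature_vector(win)
  expect_length(v2, 56)
  expect_true(any(is.na(v2))) # e.g. SDANN needs two 30-s windows
  expect_identical(names(v2), names(v))
  # normalized powers are complementary when defined
  if (!is.na(v[["fw_nLF"]])) {
    expect_equal(v[["fw_nLF"]] + v[["fw_nHF"]], 1, tolerance = 1e-9)
  }
  expect_true(all(v[c("fw_pLF", "fw_pHF")] >= 0 &
                  v[c("fw_pLF", "fw_pHF")] <= 100, na.rm = TRUE))
})

test_that("detection quality holds on the full synthetic session", {
  b <- autonomic_bundle()
  clean <- preprocess_ecg(b$ecg, 256)
  pk <- detect_r_peaks(clean, 256)
  truth <- b$ledger$r_times
  d <- vapply(truth, function(t) min(abs(pk$time - t)), numeric(1))
  d2 <- vapply(pk$time, function(t) min(abs(truth - t)), numeric(1))
  expect_gte(mean(d < 0.02), 0.99)
  expect_gte(mean(d2 < 0.02), 0.99)
})
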