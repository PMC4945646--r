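test_that("global field power matches its algebraic identity", {
  # hand example: two electrodes at 0 and 2 microvolts
  expect_equal(global_field_power(matrix(c(0, 2), 2, 1)), 2)
  # equipotential -> 0; homogeneity in the potentials
  expect_equal(global_field_power(matrix(1, 5, 3)), rep(0, 3))
  m <- withr::with_seed(1, matrix(rnorm(12 * 50), 12, 50))
  expect_equal(global_field_power(3 * m), 3 * global_field_power(m))
  # exact identity with the cross-electrode dispersion, random inputs
  for (ne in c(2, 5, 12)) {
    x <- withr::with_seed(ne, matrix(rnorm(ne * 40), ne, 40))
    oracle <- sqrt(2 * (ne - 1)) * apply(x, 2, sd)
    expect_equal(global_field_power(x), oracle, tolerance = 1e-12)
  }
})

test_that("the Zscore index standardizes against its baseline", {
  base <- withr::with_seed(2, rgamma(1000, 4))
  expect_equal(zscore_series(rep(mean(base), 7), base), rep(0, 7))
  expect_equal(zscore_series(mean(base) + sd(base), base), 1)
  stim <- withr::with_seed(3, rgamma(50, 4))
  expect_equal(zscore_series(5 * stim, 5 * base),
               zscore_series(stim, base), tolerance = 1e-12)
  expect_error(zscore_series(stim, rep(1, 100)), "zero variance")
})

test_that("peak counting matches a brute-force excursion scan", {
  t <- seq(0, 30, by = 0.1)
  z <- rep(0, length(t))
  # five excursions with apexes at 2, 6, 11, 19, 27 s
  apexes <- c(2, 6, 11, 19, 27)
  for (a in apexes) z[abs(t - a) < 0.5] <- 4 - 4 * abs(t[abs(t - a) < 0.5] - a)
  bw <- list(c(5.5, 6.5), c(18.5, 19.5)) # contain apexes 6 and 19
  pk <- count_peaks(z, t, bw, threshold = 3)
  expect_equal(pk$pn_total, 5L)
  expect_equal(pk$pn_brand, 2L)
  expect_equal(count_peaks(rep(2.9, length(t)), t, bw)$pn_total, 0L)
  # raising the threshold never increases the count
  thresholds <- c(1, 2, 3, 3.5, 3.9)
  counts <- vapply(thresholds,
                   function(th) count_peaks(z, t, bw, th)$pn_total,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the interest index is the brand share of peaks", {
  expect_equal(interest_index(2, 5), 0.4)
  expect_equal(interest_index(0, 7), 0)
  expect_true(is.na(interest_index(0, 0)))
  expect_error(interest_index(3, 2))
})

test_that("memorization curves normalize and average correctly", {
  m <- 40
  g <- matrix(2, 6, m) # constant GFP for six subjects
  mi <- memorization_curves(g, rep(c(TRUE, FALSE), 3), "theta")
  expect_equal(unique(round(mi$value, 12)), 1 / m)
  # per-subject normalization sums to one before averaging
  g2 <- withr::with_seed(4, matrix(rgamma(6 * m, 2), 6, m))
  norm <- t(apply(g2, 1, function(x) x / sum(x)))
  expect_equal(rowSums(norm), rep(1, 6))
  # identical subjects: group curve equals the individual curve
  g3 <- matrix(rep(g2[1, ], each = 4), 4, m)
  mi3 <- memorization_curves(g3, c(TRUE, TRUE, FALSE, FALSE), "alpha")
  one <- memorization_curves(g3[c(1, 1), , drop = FALSE], c(TRUE, FALSE),
                             "alpha")
  expect_equal(mi3$value, one$value, tolerance = 1e-9)
  # an empty group is reported unavailable
  mi4 <- memorization_curves(g2, rep(TRUE, 6), "theta")
  expect_equal(attr(mi4, "unavailable"), "forget")
})

test_that("pleasantness curves are right-minus-left asymmetries", {
  m <- 60
  l <- withr::with_seed(5, matrix(rgamma(4 * m, 2), 4, m))
  r <- l + 0.7
  pc <- pleasantness_curves(l, r, c(TRUE, TRUE, FALSE, FALSE), "theta")
  expect_equal(unique(round(pc$value, 6)), 0.7)
  # identical hemispheres -> zero
  p0 <- pleasantness_curves(l, l, c(TRUE, FALSE, TRUE, FALSE), "alpha")
  expect_equal(max(abs(p0$value)), 0)
  # swapping hemispheres flips the sign
  ps <- pleasantness_curves(r, l, c(TRUE, TRUE, FALSE, FALSE), "theta")
  expect_equal(ps$value, -pc$value, tolerance = 1e-9)
})

test_that("Welch band power behaves like a spectral density", {
  fs <- 256
  t <- seq_len(8 * fs) / fs
  spec <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(spec$freq[2] - spec$freq[1], 2) # 128-sample windows at 256 Hz
  alpha <- welch_band_power(sin(2 * pi * 10 * t), fs, 8, 12)
  total <- welch_band_power(sin(2 * pi * 10 * t), fs, 1, 40)
  expect_gte(alpha / total, 0.9)
  # white noise: band power proportional to bandwidth
  x <- withr::with_seed(6, rnorm(60 * fs))
  p_beta <- welch_band_power(x, fs, 13, 24)  # 11 Hz wide
  p_alpha <- welch_band_power(x, fs, 8, 12)  # 4 Hz wide
  expect_lt(abs(p_beta / p_alpha - 11 / 4) / (11 / 4), 0.35)
  expect_equal(welch_band_power(numeric(256), fs, 1, 40), 0)
})

test_that("per-instance EEG feature vectors have the canonical lengths", {
  pp <- eeg_preprocessed()
  tl <- small_timeline()
  ads <- ad_blocks(tl)
  fv <- eeg_feature_vectors(pp$eeg, 256, tl, ads$ad_id[1], pp$sample_mask)
  expect_length(fv$gfp_zscore, 18)
  expect_length(fv$psd, 72)
  expect_length(fv$index, 8)
  expect_length(fv$all, 98)
  expect_identical(fv$all, c(fv$gfp_zscore, fv$psd, fv$index))
  expect_false(anyDuplicated(names(fv$all)) > 0)
  expect_true(all(fv$psd >= 0))
  # log of a non-positive mean Zscore is a missing value, not an error
  neg <- fv$gfp_zscore
  z_means <- neg[grepl("^z_mean_", names(neg))]
  logs <- neg[grepl("^logz_mean_", names(neg))]
  bad <- z_means <= 0
  expect_true(all(is.na(logs[bad])))
  expect_true(all(is.finite(logs[!bad])))
  # peak-count invariants
  expect_lte(fv$index[["Peaks_Brand_Theta"]], fv$index[["Peaks_Theta"]])
  ii <- fv$index[["Index_Theta"]]
  expect_true(is.na(ii) || (ii >= 0 && ii <= 1))
})

test_that("brainrate is the power-weighted band-centre mean", {
  p <- c(delta = 0, theta = 0, alpha = 1, beta = 0)
  expect_equal(brainrate(p), 10)
  p2 <- c(delta = 1, theta = 0, alpha = 0, beta = 1)
  expect_equal(brainrate(p2), (2 + 18.5) / 2)
  p3 <- withr::with_seed(7, c(delta = runif(1), theta = runif(1),
                              alpha = runif(1), beta = runif(1)))
  expect_gte(brainrate(p3), 2)
  expect_lte(brainrate(p3), 18.5)
  expect_error(brainrate(c(delta = 0, theta = 0, alpha = 0, beta = 0)))
})

test_that("frontal theta gain separates classes in mean_Theta", {
  # the generator raises frontal theta for the positive class; with the
  # stimulus/baseline design this must be detectable across instances
  tl <- small_timeline()
  ads <- ad_blocks(tl)
  vals <- list(positive = c(), neutral_or_negative = c())
  for (s in 1:5) {
    prof <- subject_profile(paste0("m", s), tl, rng_seed = 100 + s)
    b <- generate_subject(tl, prof, signals = "eeg",
                          eeg_args = list(blink_rate = 0))
    pp <- preprocess_eeg(b$eeg, 256, ica = FALSE)
    for (i in seq_len(nrow(ads))) {
      fv <- eeg_feature_vectors(pp$eeg, 256, tl, ads$ad_id[i],
                                pp$sample_mask)
      cls <- prof$ad_labels[[ads$ad_id[i]]]
      key <- if (cls %in% c("positive", "unlabeled")) "positive" else
        "neutral_or_negative"
      vals[[key]] <- c(vals[[key]], fv$index[["mean_Theta"]])
    }
  }
  tst <- t.test(vals$positive, vals$neutral_or_negative,
                alternative = "greater")
  expect_lt(tst$p.value, 0.05)
})
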