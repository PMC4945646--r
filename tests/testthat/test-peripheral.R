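test_that("extrema detection alternates and handles plateaus", {
  # triangular pulse: one maximum with flanking minima
  pulse <- c(seq(0, 1, length.out = 20), seq(1, 0, length.out = 20)[-1])
  ex <- detect_extrema(pulse, fs = 32)
  expect_equal(sum(ex$type == "max"), 1)
  expect_equal(sum(ex$type == "min"), 2)
  expect_true(all(ex$type == c("min", "max", "min")))
  # constant signal: nothing
  expect_equal(nrow(detect_extrema(rep(2, 100), 32)), 0)
  # plateau at the top resolves to its midpoint
  plat <- c(0:5, rep(5, 9), 5:0)
  exp_mid <- detect_extrema(plat, fs = 1)
  apex <- exp_mid[exp_mid$type == "max", ]
  expect_equal(apex$time, (7 + 15) / 2 / 1)
  # strict alternation on a noisy wiggle
  x <- withr::with_seed(1, cumsum(rnorm(400)))
  exn <- detect_extrema(x, 32)
  if (nrow(exn) > 1) {
    expect_true(all(exn$type[-1] != exn$type[-nrow(exn)]))
    expect_true(all(diff(exn$time) > 0))
  }
})

test_that("GSR features match hand computation on a toy trace", {
  fs <- 32
  t <- seq(0, 30, by = 1 / fs)
  x <- rep(2, length(t))
  shape <- physioad:::scr_shape(seq(0, 8, by = 1 / fs))
  onsets <- c(4, 14, 24)
  amps <- c(0.5, 0.3, 0.8)
  for (i in 1:3) {
    idx <- round(onsets[i] * fs) + seq_along(shape) - 1L
    idx <- idx[idx <= length(t)]
    x[idx] <- x[idx] + amps[i] * shape[seq_along(idx)]
  }
  f <- gsr_features(x, fs)
  expect_length(f, 10)
  expect_equal(f[["gsr_n_maxima"]], 3)
  expect_equal(f[["gsr_peaks_per_time"]], 3 / (length(x) / fs))
  expect_equal(f[["gsr_variance"]], f[["gsr_sd"]]^2, tolerance = 1e-12)
  expect_equal(f[["gsr_range"]], f[["gsr_max"]] - f[["gsr_min"]],
               tolerance = 1e-12)
  # mean rise: each maximum paired with the preceding minimum
  ex <- detect_extrema(x, fs, min_prominence = 0.02)
  mx <- ex[ex$type == "max", ]
  mn <- ex[ex$type == "min", ]
  rises <- vapply(seq_len(nrow(mx)), function(i) {
    prev <- mn$value[mn$time < mx$time[i]]
    mx$value[i] - prev[length(prev)]
  }, numeric(1))
  expect_equal(f[["gsr_mean_rise"]], mean(rises))
  # constant segment: degenerate values
  f0 <- gsr_features(rep(1.5, 200), fs)
  expect_equal(unname(f0[c("gsr_variance", "gsr_n_maxima",
                           "gsr_peaks_per_time", "gsr_range")]),
               c(0, 0, 0, 0))
})

test_that("respiration features count breaths and spacing", {
  fs <- 32
  t <- seq(1 / fs, 60, by = 1 / fs)
  f <- rsp_features(sin(2 * pi * 0.25 * t), fs)
  expect_length(f, 6)
  expect_equal(f[["rsp_rate"]], 15)
  expect_equal(f[["rsp_ibi_longest"]], 4, tolerance = 0.05)
  expect_equal(f[["rsp_ibi_shortest"]], 4, tolerance = 0.05)
  expect_gte(f[["rsp_ibi_longest"]], f[["rsp_ibi_shortest"]])
  f0 <- rsp_features(rep(0.2, 500), fs)
  expect_equal(f0[["rsp_rate"]], 0)
  expect_true(is.na(f0[["rsp_ibi_longest"]]))
})

test_that("amplitude features are affine-equivariant", {
  fs <- 32
  x <- autonomic_bundle()$gsr[1:(60 * fs)]
  x <- morphological_filter(x, 0.5, fs)
  f1 <- gsr_features(x, fs)
  f2 <- gsr_features(2 * x + 3, fs, min_prominence = 0.04)
  expect_equal(f2[["gsr_mean"]], 2 * f1[["gsr_mean"]] + 3)
  expect_equal(f2[["gsr_variance"]], 4 * f1[["gsr_variance"]])
  expect_equal(f2[["gsr_sd"]], 2 * f1[["gsr_sd"]])
  expect_equal(f2[["gsr_range"]], 2 * f1[["gsr_range"]])
  expect_equal(f2[["gsr_n_maxima"]], f1[["gsr_n_maxima"]])
})

test_that("the GSR peak rate tracks the generator's event rate", {
  tl <- small_timeline()
  rates <- c(0.04, 0.08, 0.12, 0.2, 0.3)
  mean_rate <- vapply(seq_along(rates), function(i) {
    prof <- subject_profile("r", tl, class_effects = class_effects_null(),
                            rng_seed = 50, subject_sd = 0)
    g <- physioad:::simulate_gsr(tl, prof, seed = 123,
                                 base_rate_ad = rates[i],
                                 base_rate_doc = rates[i])
    sm <- morphological_filter(g$gsr, 0.5, 32)
    gsr_features(sm, 32)[["gsr_peaks_per_time"]]
  }, numeric(1))
  expect_true(all(diff(mean_rate) > 0))
})
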