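test_that("sliding detrend removes constants and ramps, preserves oscillations", {
  fs <- 100
  expect_true(all(abs(sliding_detrend(rep(50, fs * 12), fs)) < 1e-9))

  ramp <- seq(0, 500, length.out = fs * 12)
  expect_lt(max(abs(sliding_detrend(ramp, fs))), 1e-6 * max(abs(ramp)))

  # 1 Hz sine survives within 5% RMS of an independent per-window lm oracle
  x <- make_sine(1, 60, fs)
  out <- sliding_detrend(x, fs, 3)
  oracle <- x
  w <- 3 * fs
  for (k in seq_len(length(x) %/% w)) {
    idx <- (k - 1) * w + seq_len(w)
    tt <- seq_along(idx)
    oracle[idx] <- residuals(lm(x[idx] ~ tt))
  }
  rem <- (length(x) %/% w) * w
  if (rem < length(x)) {
    idx <- (rem + 1):length(x)
    tt <- seq_along(idx)
    oracle[idx] <- residuals(lm(x[idx] ~ tt))
  }
  expect_lt(sqrt(mean((out - oracle)^2)), 1e-8)
  # a per-window linear fit removes a deterministic ~26% RMS from a 1 Hz
  # sine in 3 s windows (the fitted line correlates with t*sin(2*pi*t) over
  # whole cycles); the oscillation itself survives
  expect_lt(sqrt(mean((out - x)^2)) / sqrt(mean(x^2)), 0.3)
  expect_gt(cor(out, x), 0.95)

  expect_error(sliding_detrend(rnorm(10), 100, 3), "longer than the signal")
})

test_that("high-amplitude mask excludes whole windows, strict threshold", {
  fs <- 100
  x <- rnorm(fs * 30, sd = 30)
  expect_equal(nrow(high_amplitude_mask(x, fs)$excluded), 0L)

  x[10 * fs] <- 1000          # spike at t = 10 s -> window [9, 12) excluded
  m <- high_amplitude_mask(x, fs, 900, 3)
  expect_equal(nrow(m$excluded), 1L)
  expect_equal(unname(m$excluded[1L, ]), c(9 * fs, 12 * fs))

  x[10 * fs] <- 900           # exactly at the threshold: not excluded
  expect_equal(nrow(high_amplitude_mask(x, fs, 900, 3)$excluded), 0L)
})

test_that("combined mask keeps exactly artifact-free N2/N3 samples", {
  fs <- 64
  hyp_n3 <- hypnogram(rep("N3", 10), 30)
  n <- 10 * 30 * fs
  clean <- sample_mask(n)
  expect_false(any(mask_excluded(combine_masks(clean, hyp_n3, fs))))

  hyp_w <- hypnogram(rep("W", 10), 30)
  expect_true(all(mask_excluded(combine_masks(clean, hyp_w, fs))))

  # alternating N2/REM: exactly the REM epochs are excluded
  stages <- rep(c("N2", "REM"), 5)
  hyp_alt <- hypnogram(stages, 30)
  excl <- mask_excluded(combine_masks(clean, hyp_alt, fs))
  epoch_of <- (seq_len(n) - 1) %/% (30 * fs) + 1
  expect_equal(excl, stages[epoch_of] == "REM")

  # artifact ranges are excluded on top of the stage restriction
  art <- sample_mask(n, cbind(0, 3 * fs))
  excl2 <- mask_excluded(combine_masks(art, hyp_alt, fs))
  expect_true(all(excl2[1:(3 * fs)]))
})

test_that("slow band-pass matches the analytic Butterworth magnitude", {
  fs <- 200
  t_keep <- 3000:9000  # interior samples, away from edges
  for (probe in list(c(1, 0.95, 1.0), c(20, 0, 0.01))) {
    x <- make_sine(probe[1], 60, fs)
    amp <- max(abs(bandpass_slow(x, fs)[t_keep]))
    expect_gte(amp, probe[2])
    expect_lte(amp, probe[3] + 1e-5)
    # independent oracle: squared analog Butterworth band-pass magnitude
    g2 <- butter_bp_gain2(probe[1], 0.16, 4, 6)
    expect_lt(abs(amp - g2), 0.01)
  }
  expect_error(bandpass_slow(rnorm(100), 7), "too low")
})

test_that("spindle band-passes separate the bands and exclude 13.5-14.5 Hz", {
  fs <- 200
  t_keep <- 2000:8000
  amp_in <- function(f, band) max(abs(bandpass_spindle(
    make_sine(f, 50, fs), fs, band)[t_keep]))

  expect_gte(amp_in(12, "late_fast"), 0.9)
  expect_lte(amp_in(12, "early_fast"), 0.1)
  expect_gte(amp_in(16, "early_fast"), 0.9)
  expect_lte(amp_in(16, "late_fast"), 0.1)
  # the exclusion gap: 14 Hz attenuated in BOTH bands vs band-center gain
  expect_lt(amp_in(14, "late_fast"), 0.3 * amp_in(12, "late_fast"))
  expect_lt(amp_in(14, "early_fast"), 0.3 * amp_in(16, "early_fast"))
  # magnitude-response oracle for in-band and cross-band probes
  expect_lt(abs(amp_in(12, "late_fast") - butter_bp_gain2(12, 10, 13.5, 3)), 0.02)
  expect_lt(abs(amp_in(12, "early_fast") - butter_bp_gain2(12, 14.5, 18, 3)), 0.02)

  expect_error(bandpass_spindle(rnorm(100), 30, "early_fast"), "Nyquist")
})

test_that("filtering is zero-phase and linear", {
  fs <- 128
  x <- make_sine(2, 40, fs)
  y <- bandpass_slow(x, fs)
  cc <- ccf(y[1000:4000], x[1000:4000], lag.max = 5, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)

  x12 <- make_sine(12, 40, fs)
  y12 <- bandpass_spindle(x12, fs, "late_fast")
  cc12 <- ccf(y12[1000:4000], x12[1000:4000], lag.max = 5, plot = FALSE)
  expect_lte(abs(cc12$lag[which.max(cc12$acf)]), 1)

  set.seed(2)
  a <- rnorm(fs * 20); b <- rnorm(fs * 20)
  lhs <- bandpass_slow(2 * a + 3 * b, fs)
  rhs <- 2 * bandpass_slow(a, fs) + 3 * bandpass_slow(b, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("envelope and moving RMS behave on analytic cases", {
  fs <- 200
  x <- make_sine(12, 10, fs, amp = 20)
  env <- upper_envelope(x)
  core <- env[(2 * fs):(8 * fs)]
  expect_true(all(abs(core - 20) / 20 < 0.05))

  expect_equal(upper_envelope(numeric(128) + 0), rep(0, 128))

  # amplitude-modulated sine: envelope tracks the modulator within 5% RMS
  tt <- seq(0, 10, by = 1 / fs)
  mod <- 10 * (0.55 + 0.45 * cos(2 * pi * 0.5 * tt))
  x2 <- mod * sin(2 * pi * 12 * tt)
  env2 <- upper_envelope(x2)
  sel <- (2 * fs):(8 * fs)
  expect_lt(sqrt(mean((env2[sel] - mod[sel])^2)) / sqrt(mean(mod[sel]^2)), 0.05)

  expect_equal(moving_rms(rep(3, 200), 21), rep(3, 200))
})
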