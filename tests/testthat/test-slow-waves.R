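test_that("half-wave pairing finds the analytic candidates of pure tones", {
  fs <- 200
  # 1 Hz sine, 10 s: down-crossings at 0.5, 1.5, ..., 9.5 -> 9 complete
  # trough-then-peak pairs of duration 1.0 s
  x <- make_sine(1, 10, fs, amp = 80)
  cand <- find_half_wave_pairs(x, fs)
  expect_equal(nrow(cand), 9L)
  expect_true(all(abs(cand$duration_s - 1.0) <= 2 / fs))
  expect_true(all(abs(cand$trough_uv + 80) < 1))
  expect_true(all(abs(cand$peak_uv - 80) < 1))
  expect_true(all(cand$t_down_zc_s < cand$t_trough_s &
                    cand$t_trough_s < cand$t_up_zc_s &
                    cand$t_up_zc_s < cand$t_peak_s &
                    cand$t_peak_s < cand$t_end_zc_s))

  # outside the 0.4-4 Hz full-wave window: nothing
  expect_equal(nrow(find_half_wave_pairs(make_sine(0.2, 20, fs), fs)), 0L)
  expect_equal(nrow(find_half_wave_pairs(make_sine(6, 10, fs), fs)), 0L)
  expect_equal(nrow(find_half_wave_pairs(numeric(fs * 10), fs)), 0L)
})

test_that("candidates touching masked ranges are dropped", {
  fs <- 100
  x <- make_sine(1, 20, fs, amp = 50)
  mask <- sample_mask(length(x), cbind(5 * fs, 8 * fs))
  cand <- find_half_wave_pairs(x, fs, mask)
  # no retained candidate overlaps [5, 8) s
  expect_true(all(cand$t_end_zc_s <= 5 | cand$t_down_zc_s >= 8))
  expect_lt(nrow(cand), 19L)
})

test_that("amplitude selection implements median rule, ceiling and SD gate", {
  two <- data.frame(t_down_zc_s = c(0, 2), t_trough_s = c(0.3, 2.3),
                    trough_uv = c(-50, -100), t_up_zc_s = c(0.5, 2.5),
                    t_peak_s = c(0.7, 2.7), peak_uv = c(40, 80),
                    t_end_zc_s = c(1, 3), duration_s = c(1, 1))
  kept <- amplitude_select(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$trough_uv, -100)

  # ties at the median survive (inclusive boundary)
  tie <- two; tie$trough_uv <- c(-60, -60); tie$peak_uv <- c(50, 50)
  expect_equal(nrow(amplitude_select(tie)), 2L)

  # amplitude ceiling: a 250 uV trough is removed even if top-50%
  big <- two; big$trough_uv[2] <- -250
  expect_false(any(amplitude_select(big)$trough_uv == -250))

  # 4-SD rejection on the selected population: population of troughs
  # ~N(-60, 5) (peaks comfortably uniform) plus one far outlier
  set.seed(31)
  n <- 100
  pop <- data.frame(t_down_zc_s = seq_len(n + 1) * 2,
                    t_trough_s = seq_len(n + 1) * 2 + 0.3,
                    trough_uv = c(rnorm(n, -60, 5), -95),
                    t_up_zc_s = seq_len(n + 1) * 2 + 0.5,
                    t_peak_s = seq_len(n + 1) * 2 + 0.7,
                    peak_uv = rep(60, n + 1),
                    t_end_zc_s = seq_len(n + 1) * 2 + 1,
                    duration_s = rep(1, n + 1))
  sel <- amplitude_select(pop)
  # direct oracle: the selected population's mean/SD, one pass
  msel <- pop[abs(pop$trough_uv) >= median(abs(pop$trough_uv)), ]
  expect_gt(abs(-95 - mean(msel$trough_uv)), 4 * sd(msel$trough_uv))
  expect_false(any(sel$trough_uv == -95))
  # a 6-SD injection is always removed
  expect_false(any(amplitude_select(pop)$trough_uv < -90))

  expect_error(amplitude_select(two[0, ]), "at least one")
})

test_that("amplitude selection equals a sort/median oracle on random sets", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    cand <- data.frame(t_down_zc_s = seq_len(n), t_trough_s = seq_len(n) + 0.3,
                       trough_uv = -runif(n, 5, 150),
                       t_up_zc_s = seq_len(n) + 0.5,
                       t_peak_s = seq_len(n) + 0.7,
                       peak_uv = runif(n, 5, 150),
                       t_end_zc_s = seq_len(n) + 1, duration_s = 1)
    got <- amplitude_select(cand)
    # independent oracle: explicit sort-based medians, then ceiling, then SD
    mt <- sort(abs(cand$trough_uv))
    mp <- sort(cand$peak_uv)
    med_t <- median(mt); med_p <- median(mp)
    o <- cand[abs(cand$trough_uv) >= med_t & cand$peak_uv >= med_p, ]
    o <- o[abs(o$trough_uv) <= 200 & o$peak_uv <= 200, ]
    keep <- abs(o$trough_uv - mean(o$trough_uv)) <= 4 * sd(o$trough_uv) &
      abs(o$peak_uv - mean(o$peak_uv)) <= 4 * sd(o$peak_uv)
    expect_equal(got$t_trough_s, o$t_trough_s[keep])
  }
})

test_that("detected slow waves recover injected events and invariants hold", {
  nt <- night_2h(42)
  sw <- nt$sw
  sc <- score_detection(sw$t_trough_s, nt$sim$truth$slow_waves$t_trough_s, 0.25)
  expect_gte(sc$recall, 0.9)

  # every retained event satisfies the event invariants
  expect_true(all(sw$trough_uv < 0 & sw$peak_uv > 0))
  expect_true(all(sw$duration_s >= 0.25 & sw$duration_s <= 2.5))
  expect_true(all(abs(sw$trough_uv) <= 200 & abs(sw$peak_uv) <= 200))
  expect_true(all(diff(sw$t_trough_s) > 0))
  expect_true(all(sw$stage %in% c("N2", "N3")))

  # at most ~half the candidates survive selection
  fs <- nt$sim$recording$sampling_rate_hz
  det <- sliding_detrend(nt$sim$recording$samples, fs)
  mask <- combine_masks(high_amplitude_mask(det, fs), nt$sim$hypnogram, fs)
  cand <- find_half_wave_pairs(bandpass_slow(det, fs), fs, mask)
  expect_lte(nrow(sw), 0.52 * nrow(cand))

  # determinism: identical inputs give identical event lists
  sw2 <- detect_slow_waves(nt$sim$recording, nt$sim$hypnogram)
  expect_identical(sw, sw2)
})

test_that("stage restriction and amplitude scale invariance hold", {
  cfg <- quick_cfg()
  sim <- simulate_recording(cfg)

  # an all-REM hypnogram yields no events
  hyp_rem <- hypnogram(rep("REM", length(sim$hypnogram$stages)), 30)
  expect_equal(nrow(detect_slow_waves(sim$recording, hyp_rem)), 0L)

  # scaling all amplitudes up (keeping every wave below the 200 uV ceiling)
  # leaves the detected set unchanged: selection is rank-based
  sw1 <- detect_slow_waves(sim$recording, sim$hypnogram)
  k <- min(1.9, 190 / max(abs(c(sw1$trough_uv, sw1$peak_uv))))
  expect_gt(k, 1)
  rec2 <- eeg_recording(sim$recording$samples * k, cfg$sampling_rate_hz)
  sw2 <- detect_slow_waves(rec2, sim$hypnogram)
  expect_equal(sw2$t_trough_s, sw1$t_trough_s)
  expect_equal(sw2$trough_uv, k * sw1$trough_uv, tolerance = 1e-8)
})
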