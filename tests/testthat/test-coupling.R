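test_that("coupling window, buffer and ambiguity rules classify correctly", {
  sw <- sw_row(100)
  # spindle onset 0.5 s after the trough -> LF_SW with lag 0.5
  r1 <- classify_coupling(sw, sp_row(100.5), no_spindles())
  expect_equal(nrow(r1$coupled), 1L)
  expect_equal(r1$coupled$subtype, "LF_SW")
  expect_equal(r1$coupled$lag_s, 0.5)
  expect_equal(nrow(r1$unclassified), 0L)

  # onset 0.1 s after the trough: inside the 0.2 s buffer -> unclassified
  r2 <- classify_coupling(sw, sp_row(100.1), no_spindles())
  expect_equal(nrow(r2$coupled), 0L)
  expect_equal(nrow(r2$unclassified), 1L)

  # spindles of both bands in the window -> ambiguous -> unclassified
  r3 <- classify_coupling(sw, sp_row(100.4),
                          sp_row(100.6, band = "early_fast"))
  expect_equal(nrow(r3$coupled), 0L)
  expect_equal(nrow(r3$unclassified), 1L)

  # window edges are inclusive
  r4 <- classify_coupling(sw, sp_row(101.5), no_spindles())
  expect_equal(r4$coupled$lag_s, 1.5)

  expect_error(classify_coupling(rbind(sw_row(200), sw_row(100)),
                                 sp_row(100.5), no_spindles()),
               "sorted")
})

test_that("each spindle couples at most once; earliest trough claims it", {
  sws <- rbind(sw_row(100), sw_row(100.6))
  one_sp <- sp_row(100.9)  # in both windows
  r <- classify_coupling(sws, one_sp, no_spindles())
  expect_equal(nrow(r$coupled), 1L)
  expect_equal(r$coupled$sw_t_trough_s, 100)
  expect_equal(nrow(r$unclassified), 1L)
  expect_equal(r$unclassified$t_trough_s, 100.6)
})

test_that("coupling partitions the slow waves on random synthetic sets", {
  set.seed(21)
  for (rep in 1:10) {
    n_sw <- sample(10:40, 1)
    troughs <- sort(runif(n_sw, 0, 1800))
    sws <- do.call(rbind, lapply(troughs, sw_row))
    lf <- do.call(rbind, lapply(sort(runif(sample(5:25, 1), 0, 1800)), sp_row))
    ef <- do.call(rbind, lapply(sort(runif(sample(5:25, 1), 0, 1800)),
                                function(t) sp_row(t, band = "early_fast")))
    r <- classify_coupling(sws, lf, ef)
    expect_equal(nrow(r$coupled) + nrow(r$unclassified), n_sw)
    if (nrow(r$coupled)) {
      expect_true(all(r$coupled$lag_s >= 0.2 & r$coupled$lag_s <= 1.5))
      expect_true(all(r$coupled$subtype ==
                        ifelse(r$coupled$sp_band == "late_fast", "LF_SW", "EF_SW")))
      # no spindle appears twice
      expect_false(any(duplicated(
        paste(r$coupled$sp_band, r$coupled$sp_t_onset_s))))
    }
  }
})

test_that("peri-event and baseline segment windows are placed exactly", {
  fs <- 200
  x <- seq_len(fs * 30)  # ramp: sample value identifies its index
  ev <- data.frame(t_trough_s = 10)
  ps <- peri_event_segments(x, ev, fs, 2.5)
  expect_equal(ncol(ps$segments), 1000L)
  expect_equal(ps$segments[1, 1], 7.5 * fs + 1)    # covers [7.5, 12.5)
  expect_equal(ps$n_dropped, 0L)

  # too close to the start: dropped and counted
  ps2 <- peri_event_segments(x, data.frame(t_trough_s = c(1, 10, 15)), fs, 2.5)
  expect_equal(nrow(ps2$segments), 2L)
  expect_equal(ps2$n_dropped, 1L)
  expect_equal(ps2$kept, c(2L, 3L))

  # baseline immediately precedes the peri window: [12.5, 17.5) for t = 20
  all_sw <- data.frame(t_trough_s = c(20))
  bs <- baseline_segments(x, data.frame(t_trough_s = 20), all_sw, fs, 2.5)
  expect_equal(bs$segments[1, 1], 12.5 * fs + 1)

  # a contaminating trough at 15 s discards that baseline
  all_sw2 <- data.frame(t_trough_s = c(15, 20))
  bs2 <- baseline_segments(x, data.frame(t_trough_s = 20), all_sw2, fs, 2.5)
  expect_equal(nrow(bs2$segments), 0L)
  expect_equal(bs2$n_dropped, 1L)

  # out of range at the recording start
  bs3 <- baseline_segments(x, data.frame(t_trough_s = 3), all_sw, fs, 2.5)
  expect_equal(nrow(bs3$segments), 0L)
})

test_that("Morlet maps use the standard 65-frequency grid and locate pure tones", {
  fs <- 200
  seg <- make_sine(12, 5, fs)[1:1000]
  m <- morlet_tfr(seg, fs)
  expect_equal(length(m$freqs_hz), 65L)
  expect_equal(range(m$freqs_hz), c(4, 20))
  peak_row <- m$freqs_hz[which.max(rowMeans(m$values[, 300:700]))]
  expect_lte(abs(peak_row - 12), 0.25)
  # unit-amplitude tone maps to ~1 at its own frequency
  expect_lt(abs(max(m$values[which(m$freqs_hz == 12), 300:700]) - 1), 0.05)

  z <- morlet_tfr(numeric(1000), fs)
  expect_true(all(z$values == 0))
})

test_that("baseline normalization equals direct-loop oracles", {
  fs <- 100
  set.seed(17)
  mk <- function(v) tfr_map(v, seq(4, 20, 0.25), seq(0, 4.99, by = 0.01))
  ev_maps <- lapply(1:3, function(i) mk(matrix(runif(65 * 500, 1, 2), 65)))
  ba_maps <- lapply(1:2, function(i) mk(matrix(runif(65 * 500, 1, 2), 65)))

  # identical events and baselines: constant maps normalize to exactly 1
  const <- lapply(1:3, function(i) mk(matrix(1.5, 65, 500)))
  expect_true(all(abs(normalize_and_average(const, const)$values - 1) < 1e-12))
  ones <- normalize_and_average(ev_maps, ev_maps)
  # direct two-loop oracle
  oracle <- matrix(0, 65, 500)
  for (fi in 1:65) {
    base_mean <- mean(vapply(ba_maps, function(m) mean(m$values[fi, ]), 1))
    for (ti in 1:500) {
      oracle[fi, ti] <- mean(vapply(ev_maps, function(m) m$values[fi, ti], 1)) /
        base_mean
    }
  }
  norm <- normalize_and_average(ev_maps, ba_maps)
  expect_equal(norm$values, oracle, tolerance = 1e-12)

  dbl <- normalize_and_average(lapply(ev_maps, function(m) mk(2 * m$values)),
                               ev_maps)
  expect_true(all(abs(dbl$values - 2 * ones$values) < 1e-9))

  # invariant to a global rescaling of both inputs
  resc <- normalize_and_average(lapply(ev_maps, function(m) mk(7 * m$values)),
                                lapply(ba_maps, function(m) mk(7 * m$values)))
  expect_equal(resc$values, norm$values, tolerance = 1e-12)

  expect_error(normalize_and_average(list(), ba_maps), "at least one")
})

test_that("ROI power averages inclusive grid rectangles", {
  freqs <- seq(4, 20, 0.25)
  times <- seq(-2.5, 2.495, by = 0.005)
  uni <- tfr_map(matrix(3.7, length(freqs), length(times)), freqs, times)
  roi <- list(f_lo_hz = 10, f_hi_hz = 13.5, t_lo_s = 0.2, t_hi_s = 1.5)
  expect_equal(roi_power(uni, roi), 3.7)

  # single-cell ROI returns that cell
  v <- matrix(runif(length(freqs) * length(times)), length(freqs))
  m <- tfr_map(v, freqs, times)
  cell <- list(f_lo_hz = 12, f_hi_hz = 12, t_lo_s = times[500],
               t_hi_s = times[500])
  expect_equal(roi_power(m, cell), v[which(freqs == 12), 500])

  # checkerboard vs direct summation oracle
  chk <- tfr_map(outer(seq_along(freqs), seq_along(times),
                       function(i, j) (i + j) %% 2), freqs, times)
  fi <- freqs >= roi$f_lo_hz & freqs <= roi$f_hi_hz
  ti <- times >= roi$t_lo_s & times <= roi$t_hi_s
  expect_equal(roi_power(chk, roi), mean(chk$values[fi, ti]))

  expect_error(roi_power(uni, list(f_lo_hz = 30, f_hi_hz = 40,
                                   t_lo_s = 0, t_hi_s = 1)), "outside")
})
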