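# Shared synthetic fixtures, memoised so expensive nights are simulated and
# detected once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A short desk-scale night: 30 min at 128 Hz, one NREM cycle.
quick_cfg <- function(...) {
  sim_config(duration_h = 0.5, sampling_rate_hz = 128, n_nrem_cycles = 1,
             seed = 11, ...)
}

# A richer night used by several detection tests: 2 h, 128 Hz, two cycles.
night_2h <- function(seed = 42) {
  memo(paste0("night2h_", seed), {
    cfg <- sim_config(duration_h = 2, sampling_rate_hz = 128,
                      n_nrem_cycles = 2, seed = seed)
    sim <- simulate_recording(cfg)
    sw <- detect_slow_waves(sim$recording, sim$hypnogram)
    lf <- detect_spindles(sim$recording, sim$hypnogram, "late_fast")
    ef <- detect_spindles(sim$recording, sim$hypnogram, "early_fast")
    list(cfg = cfg, sim = sim, sw = sw, lf = lf, ef = ef,
         coupling = classify_coupling(sw, lf, ef))
  })
}

# Multi-subject study fixture: a small two-group cohort written through the
# real EDF path, memoised for the pipeline and end-to-end tests.
study_dir <- function() {
  memo("study_dir", {
    dir <- file.path(tempdir(), "swacomp-study")
    dir.create(dir, showWarnings = FALSE)
    # seed-paired groups: each "old" subject is the lf-shifted counterpart
    # of a "young" night, isolating the aging knob from night-to-night
    # variability
    rows <- list()
    for (i in 1:6) {
      grp <- if (i <= 3) "young" else "old"
      cfg <- sim_config(duration_h = 2, sampling_rate_hz = 128,
                        n_nrem_cycles = 2, seed = 100 + ((i - 1) %% 3),
                        lf_shift = if (grp == "old") 0.25 else 0)
      p <- simulate_subject(cfg, dir, sprintf("s%02d", i))
      rows[[i]] <- data.frame(subject_id = sprintf("s%02d", i),
                              edf = p$edf, hypnogram = p$hypnogram,
                              group = grp, channel_pairs = "CZ:CZ")
    }
    list(dir = dir, manifest = do.call(rbind, rows))
  })
}

# Hann-windowed oscillatory burst added in place into a signal vector.
add_burst <- function(x, fs, t_onset, dur, freq, amp) {
  tt <- seq(0, dur, by = 1 / fs)
  b <- amp * 0.5 * (1 - cos(2 * pi * tt / dur)) * sin(2 * pi * freq * tt)
  idx <- round(t_onset * fs) + seq_along(b)
  x[idx] <- x[idx] + b
  x
}

# Pink noise identical in construction to the generator's background.
test_pink <- function(n, fs, scale, seed = 5, beta = 1) {
  set.seed(seed)
  white <- rnorm(n)
  f <- c(0, seq_len(n - 1)); f <- pmin(f, n - f) / n * fs
  x <- Re(fft(fft(white) * ifelse(f > 0, f^(-beta / 2), 0), inverse = TRUE)) / n
  x / sd(x) * scale
}

# Constant-frequency test tone.
make_sine <- function(freq_hz, duration_s, fs, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq_hz * seq(0, duration_s, by = 1 / fs) + phase)
}

# Analog Butterworth band-pass squared magnitude (the zero-phase filter's
# gain): independent oracle for the filter tests.
butter_bp_gain2 <- function(f, lo, hi, order) {
  w0sq <- lo * hi
  bw <- hi - lo
  (1 / (1 + ((f^2 - w0sq) / (f * bw))^(2 * order)))^2
}

# Minimal slow-wave event rows for coupling tests.
sw_row <- function(t_trough, stage = "N3", trough = -80, peak = 60) {
  data.frame(t_down_zc_s = t_trough - 0.3, t_trough_s = t_trough,
             trough_uv = trough, t_up_zc_s = t_trough + 0.3,
             t_peak_s = t_trough + 0.5, peak_uv = peak,
             t_end_zc_s = t_trough + 0.7, duration_s = 1.0, stage = stage)
}

# Minimal spindle event rows for coupling tests; empty input gives the
# empty event frame.
sp_row <- function(t_onset, band = "late_fast", dur = 1.0, peak = 12) {
  n <- length(t_onset)
  data.frame(band = rep(band, n), t_onset_s = t_onset,
             t_offset_s = t_onset + dur, duration_s = rep(dur, n),
             peak_envelope_uv = rep(peak, n),
             mean_envelope_uv = rep(peak * 0.6, n),
             t_peak_env_s = t_onset + dur / 2, range_uv = rep(2 * peak, n),
             stage = rep("N3", n))
}

no_spindles <- function() sp_row(numeric(0))
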