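# Synthetic overnight polysomnography with ground truth. The generator
# emulates the statistical structure the detection pipeline is built for:
# staged sleep with several NREM cycles, 1/f background EEG, discrete slow
# oscillations at stage-dependent rates, spindle bursts in the two fast-sigma
# bands coupled to a fraction of slow-wave troughs, stage-dependent subtype
# mixing (N3 biased late-fast, N2 biased early-fast), and an aging knob that
# shifts coupling toward the late-fast subtype.

#' Simulation configuration
#'
#' Defaults describe a clean overnight recording: 8 h at 200 Hz with four
#' NREM cycles; slow oscillations of -80 +/- 10 uV trough depth at 12 per
#' minute in N3 and 6 per minute in N2; pink (1/f) background of 15 uV
#' total RMS; 12 Hz late-fast and 16 Hz early-fast spindle bursts of
#' 11 +/- 2.5 uV coupled to slow-wave troughs with lags uniform on
#' [0.25, 1.4] s (strictly inside the 0.2-1.5 s classification window);
#' coupling probabilities N3 = (LF 0.45, EF 0.20) and N2 = (LF 0.25,
#' EF 0.35), drawn mutually exclusively per slow wave. `lf_shift` adds to the
#' late-fast coupling probability in both stages (capped so stage totals stay
#' at most 1), emulating the age-related shift toward late-fast coupling.
#'
#' @param ... Named overrides of any default field.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    duration_h = 8,
    sampling_rate_hz = 200,
    n_nrem_cycles = 4L,
    stage_epoch_s = 30,
    sw_rate_per_min = c(N2 = 6, N3 = 12),
    sw_amp_uv = c(mean = 80, sd = 10),
    sw_peak_frac = 0.75,
    sw_dur_range_s = c(0.8, 1.6),
    sw_min_gap_s = 2,
    spindle_coupling_prob = list(
      N3 = c(late_fast = 0.45, early_fast = 0.20),
      N2 = c(late_fast = 0.25, early_fast = 0.35)
    ),
    lag_range_s = c(0.25, 1.4),
    spindle_freq_hz = c(late_fast = 12, early_fast = 16),
    spindle_amp_uv = c(mean = 11, sd = 2.5),
    spindle_dur_s = c(mean = 1.2, sd = 0.25),
    uncoupled_spindle_rate_per_min = 0.5,
    noise_exponent = 1,
    noise_scale_uv = 15,
    lf_shift = 0,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (st in names(cfg$spindle_coupling_prob)) {
    p <- cfg$spindle_coupling_prob[[st]]
    if (any(p < 0) || any(p > 1) || sum(p) > 1)
      stop("coupling probabilities per stage must be in [0,1] and sum to <= 1")
  }
  if (cfg$lf_shift < 0 || cfg$lf_shift > 1) stop("lf_shift must be in [0, 1]")
  f <- cfg$spindle_freq_hz
  if (any(f >= 13.5 & f <= 14.5))
    stop("spindle carrier frequencies must avoid the 13.5-14.5 Hz exclusion band")
  if (any(cfg$sw_rate_per_min < 0)) stop("slow-wave rates must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a staged hypnogram
#'
#' Wake onset followed by `n_nrem_cycles` cycles of N1 -> N2 -> N3 -> N2 ->
#' REM, with cycle lengths scaled to fill the night (about 90 min for an 8 h,
#' 4-cycle night). The template is deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(config) {
  ep <- config$stage_epoch_s
  n_ep <- as.integer(round(config$duration_h * 3600 / ep))
  if (n_ep < 1L) stop("duration too short for one epoch")
  if (config$n_nrem_cycles == 0L) return(hypnogram(rep("W", n_ep), ep))
  w_lead <- max(1L, round(0.04 * n_ep))
  per_cycle <- (n_ep - w_lead) / config$n_nrem_cycles
  if (per_cycle < 5) stop("duration too short for the requested cycles")
  frac <- c(N1 = 0.06, N2 = 0.35, N3 = 0.25, N2 = 0.17, REM = 0.17)
  stages <- rep("W", w_lead)
  for (cyc in seq_len(config$n_nrem_cycles)) {
    lens <- round(frac * per_cycle)
    for (k in seq_along(lens)) stages <- c(stages, rep(names(frac)[k], lens[k]))
  }
  stages <- stages[seq_len(min(length(stages), n_ep))]
  if (length(stages) < n_ep) stages <- c(stages, rep("W", n_ep - length(stages)))
  hypnogram(stages, ep)
}

# 1/f^beta noise by spectral shaping of white Gaussian noise, scaled to a
# target standard deviation.
pink_noise <- function(n, fs, beta, scale) {
  if (scale <= 0) return(numeric(n))
  white <- rnorm(n)
  f <- c(0, seq_len(n - 1L))
  f <- pmin(f, n - f) / n * fs
  shape <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(fft(fft(white) * shape, inverse = TRUE)) / n
  x / sd(x) * scale
}

# One biphasic slow-oscillation cycle: negative then positive half-wave.
so_waveform <- function(duration_s, trough_uv, peak_uv, fs) {
  d1 <- duration_s / 2
  tt <- seq(0, duration_s, by = 1 / fs)
  ifelse(tt < d1,
         trough_uv * sin(pi * tt / d1),
         peak_uv * sin(pi * (tt - d1) / (duration_s - d1)))
}

# Gaussian-equivalent (Hann-windowed) spindle burst.
spindle_burst <- function(duration_s, amp_uv, freq_hz, phase, fs) {
  tt <- seq(0, duration_s, by = 1 / fs)
  amp_uv * 0.5 * (1 - cos(2 * pi * tt / duration_s)) *
    sin(2 * pi * freq_hz * tt + phase)
}

#' Simulate an overnight EEG recording with ground truth
#'
#' The signal is `1/f^beta` background noise plus injected slow oscillations
#' (biphasic single cycles at Poisson times within N2/N3 at stage-dependent
#' rates, thinned to a minimum separation) plus Hann-windowed spindle bursts
#' attached to slow-wave troughs (mutually exclusive subtype draw per slow
#' wave at the stage's coupling probabilities, lag uniform on the configured
#' support) plus a low rate of uncoupled spindles. Bitwise deterministic
#' under the configuration seed; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @param hyp Optional [hypnogram()]; defaults to
#'   `simulate_hypnogram(config)`.
#' @return List with `recording` (an [eeg_recording()]), `hypnogram`, and
#'   `truth` (list of data.frames `slow_waves`, `spindles`, `couples`).
#' @export
simulate_recording <- function(config, hyp = NULL) {
  if (is.null(hyp)) hyp <- simulate_hypnogram(config)
  fs <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_h * 3600 * fs))
  ep <- hyp$epoch_seconds

  with_seed(config$seed, {
    x <- pink_noise(n, fs, config$noise_exponent, config$noise_scale_uv)

    # stage runs in seconds
    r <- rle(hyp$stages)
    run_end <- cumsum(r$lengths) * ep
    run_start <- run_end - r$lengths * ep

    sw <- list(); sp <- list(); cp <- list()
    probs <- config$spindle_coupling_prob
    for (i in seq_along(r$values)) {
      st <- r$values[i]
      rate <- config$sw_rate_per_min[st]
      if (is.na(rate) || rate <= 0) next
      span <- c(run_start[i], run_end[i])
      n_ev <- rpois(1L, rate * diff(span) / 60)
      if (!n_ev) next
      times <- sort(runif(n_ev, span[1L], span[2L] - 2))
      if (length(times) > 1L)
        times <- times[c(TRUE, diff(times) > config$sw_min_gap_s)]
      for (t0 in times) {
        d <- runif(1L, config$sw_dur_range_s[1L], config$sw_dur_range_s[2L])
        A <- -abs(rnorm(1L, config$sw_amp_uv["mean"], config$sw_amp_uv["sd"]))
        P <- config$sw_peak_frac * abs(A)
        w <- so_waveform(d, A, P, fs)
        i0 <- as.integer(round(t0 * fs)) + 1L
        idx <- i0 + seq_along(w) - 1L
        ok <- idx >= 1L & idx <= n
        if (!any(ok)) next
        x[idx[ok]] <- x[idx[ok]] + w[ok]
        t_trough <- t0 + d / 4          # trough of the first half-wave sine
        sw[[length(sw) + 1L]] <- data.frame(
          t_trough_s = t_trough, trough_uv = A, duration_s = d, stage = st)
        sw_i <- length(sw)

        pr <- probs[[st]]
        if (is.null(pr)) next
        p_lf <- min(pr["late_fast"] + config$lf_shift, 1 - pr["early_fast"])
        p_ef <- pr["early_fast"]
        u <- runif(1L)
        band <- if (u < p_lf) "late_fast"
        else if (u < p_lf + p_ef) "early_fast"
        else NA_character_
        if (is.na(band)) next
        lag <- runif(1L, config$lag_range_s[1L], config$lag_range_s[2L])
        dur <- min(max(rnorm(1L, config$spindle_dur_s["mean"],
                             config$spindle_dur_s["sd"]), 0.8), 2.0)
        amp <- min(max(rnorm(1L, config$spindle_amp_uv["mean"],
                                   config$spindle_amp_uv["sd"]), 8), 16)
        onset <- t_trough + lag
        b <- spindle_burst(dur, amp, config$spindle_freq_hz[band],
                           runif(1L, 0, 2 * pi), fs)
        j0 <- as.integer(round(onset * fs)) + 1L
        jdx <- j0 + seq_along(b) - 1L
        okj <- jdx >= 1L & jdx <= n
        if (!any(okj)) next
        x[jdx[okj]] <- x[jdx[okj]] + b[okj]
        sp[[length(sp) + 1L]] <- data.frame(
          t_onset_s = onset, duration_s = dur, band = band, amp_uv = amp,
          stage = st)
        cp[[length(cp) + 1L]] <- data.frame(
          sw_index = sw_i, spindle_index = length(sp),
          subtype = if (band == "late_fast") "LF_SW" else "EF_SW",
          lag_s = lag)
      }
    }

    # uncoupled background spindles over NREM time, both bands
    nrem_runs <- which(r$values %in% c("N2", "N3"))
    for (i in nrem_runs) {
      span_min <- (run_end[i] - run_start[i]) / 60
      for (band in names(config$spindle_freq_hz)) {
        n_un <- rpois(1L, config$uncoupled_spindle_rate_per_min * span_min)
        if (!n_un) next
        for (t0 in runif(n_un, run_start[i], run_end[i] - 3)) {
          dur <- min(max(rnorm(1L, config$spindle_dur_s["mean"],
                               config$spindle_dur_s["sd"]), 0.8), 2.0)
          amp <- min(max(rnorm(1L, config$spindle_amp_uv["mean"],
                                     config$spindle_amp_uv["sd"]), 8), 16)
          b <- spindle_burst(dur, amp, config$spindle_freq_hz[band],
                             runif(1L, 0, 2 * pi), fs)
          j0 <- as.integer(round(t0 * fs)) + 1L
          jdx <- j0 + seq_along(b) - 1L
          okj <- jdx >= 1L & jdx <= n
          if (!any(okj)) next
          x[jdx[okj]] <- x[jdx[okj]] + b[okj]
          sp[[length(sp) + 1L]] <- data.frame(
            t_onset_s = t0, duration_s = dur, band = band, amp_uv = amp,
            stage = r$values[i])
        }
      }
    }

    bindf <- function(l, empty) if (length(l)) do.call(rbind, l) else empty
    truth <- list(
      slow_waves = bindf(sw, data.frame(t_trough_s = numeric(0),
                                        trough_uv = numeric(0),
                                        duration_s = numeric(0),
                                        stage = character(0))),
      spindles = bindf(sp, data.frame(t_onset_s = numeric(0),
                                      duration_s = numeric(0),
                                      band = character(0),
                                      amp_uv = numeric(0),
                                      stage = character(0))),
      couples = bindf(cp, data.frame(sw_index = integer(0),
                                     spindle_index = integer(0),
                                     subtype = character(0),
                                     lag_s = numeric(0)))
    )
    rownames(truth$slow_waves) <- rownames(truth$spindles) <-
      rownames(truth$couples) <- NULL
    list(recording = eeg_recording(x, fs, subject_id = "synthetic",
                                   channel_label = "CZ",
                                   reference_label = "A1"),
         hypnogram = hyp,
         truth = truth)
  })
}

#' Write a synthetic subject to disk
#'
#' Produces a standard EDF, a plain-text hypnogram and ground-truth event
#' tables, so the pipeline can be exercised through its real I/O path.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param subject_id Identifier used in file names.
#' @return List of file paths (`edf`, `hypnogram`, `truth_slow_waves`,
#'   `truth_spindles`, `truth_couples`) plus the in-memory simulation.
#' @export
simulate_subject <- function(config, out_dir, subject_id = "sim01") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_recording(config)
  paths <- list(
    edf = file.path(out_dir, paste0(subject_id, ".edf")),
    hypnogram = file.path(out_dir, paste0(subject_id, ".hyp")),
    truth_slow_waves = file.path(out_dir, paste0(subject_id, "_truth_sw.tsv")),
    truth_spindles = file.path(out_dir, paste0(subject_id, "_truth_sp.tsv")),
    truth_couples = file.path(out_dir, paste0(subject_id, "_truth_cp.tsv"))
  )
  write_edf(paths$edf, setNames(list(sim$recording$samples), "CZ-A1"),
            config$sampling_rate_hz, subject_id)
  write_hypnogram(sim$hypnogram, paths$hypnogram)
  write_event_table(sim$truth$slow_waves, paths$truth_slow_waves)
  write_event_table(sim$truth$spindles, paths$truth_spindles)
  write_event_table(sim$truth$couples, paths$truth_couples)
  c(paths, list(sim = sim))
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching, globally nearest first: candidate
#' detection/truth pairs within the tolerance are sorted by absolute time
#' difference and claimed in order. Precision is `matched / n_detected`
#' (reported as 1 with a flag when nothing was detected) and recall is
#' `matched / n_truth`.
#'
#' @param detected_times_s Detected event times (seconds).
#' @param truth_times_s Ground-truth event times (seconds).
#' @param tolerance_s Maximum |detected - truth| for a match.
#' @return List: `precision`, `recall`, `n_detected`, `n_truth`, `matches`
#'   (data.frame `truth_idx`, `detected_idx`, `dt_s`), `zero_detections`.
#' @export
score_detection <- function(detected_times_s, truth_times_s, tolerance_s) {
  stopifnot(tolerance_s > 0)
  nd <- length(detected_times_s); nt <- length(truth_times_s)
  if (!nd) {
    return(list(precision = 1, recall = if (nt) 0 else 1,
                n_detected = 0L, n_truth = nt,
                matches = data.frame(truth_idx = integer(0),
                                     detected_idx = integer(0),
                                     dt_s = numeric(0)),
                zero_detections = TRUE))
  }
  ord <- order(detected_times_s)
  dsort <- detected_times_s[ord]
  pairs <- vector("list", nt)
  for (i in seq_len(nt)) {
    lo <- findInterval(truth_times_s[i] - tolerance_s, dsort) + 1L
    hi <- findInterval(truth_times_s[i] + tolerance_s, dsort)
    if (hi >= lo) {
      j <- lo:hi
      pairs[[i]] <- data.frame(truth_idx = i, detected_idx = ord[j],
                               dt_s = dsort[j] - truth_times_s[i])
    }
  }
  pairs <- do.call(rbind, pairs)
  matches <- data.frame(truth_idx = integer(0), detected_idx = integer(0),
                        dt_s = numeric(0))
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(abs(pairs$dt_s)), , drop = FALSE]
    t_used <- rep(FALSE, nt); d_used <- rep(FALSE, nd)
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$truth_idx[k]; di <- pairs$detected_idx[k]
      if (!t_used[ti] && !d_used[di]) {
        t_used[ti] <- TRUE; d_used[di] <- TRUE
        matches <- rbind(matches, pairs[k, , drop = FALSE])
      }
    }
  }
  m <- nrow(matches)
  list(precision = m / nd, recall = if (nt) m / nt else 1,
       n_detected = nd, n_truth = nt,
       matches = matches, zero_detections = FALSE)
}
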