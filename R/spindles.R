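#' Spindle detection threshold
#'
#' The 75th percentile (linear-interpolation definition, R type 7) of a
#' centered moving-RMS series of the envelope, evaluated over analyzable
#' samples only. The moving-RMS window defaults to 0.5 s, the minimum spindle
#' length. The returned scalar is applied to the envelope itself.
#'
#' @param envelope Envelope series from [upper_envelope()].
#' @param analyzable Logical vector, `TRUE` where the sample may enter the
#'   estimate (from [combine_masks()]), or `NULL` for all samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param rms_window_s Moving-RMS window in seconds.
#' @param quantile_p Percentile (0-1).
#' @return Threshold in microvolts.
#' @export
spindle_threshold <- function(envelope, analyzable = NULL, sampling_rate_hz,
                              rms_window_s = 0.5, quantile_p = 0.75) {
  if (is.null(analyzable)) analyzable <- rep(TRUE, length(envelope))
  if (!any(analyzable)) stop("no analyzable samples for the spindle threshold")
  rms <- moving_rms(envelope, round(rms_window_s * sampling_rate_hz))
  unname(quantile(rms[analyzable], quantile_p, type = 7))
}

#' Detect sleep spindles in one band
#'
#' Pipeline: sliding detrend, artifact mask and N2/N3 stage restriction,
#' zero-phase band-pass in the requested spindle band, analytic-signal upper
#' envelope, whole-night 75th-percentile moving-RMS threshold, contiguous
#' supra-threshold segments (gaps shorter than `merge_gap_s` are bridged so
#' envelope ripple does not split a burst), a 0.5-3.0 s duration window, a
#' 40 uV band-passed peak-to-trough range artifact gate, and an 8-SD peak
#' envelope outlier rejection (computed once over the surviving events).
#' Events are stamped with the stage of their onset epoch.
#'
#' @param recording An [eeg_recording()].
#' @param hyp A paired [hypnogram()].
#' @param band `"late_fast"` (10-13.5 Hz) or `"early_fast"` (14.5-18 Hz).
#' @param config Configuration list (see [swa_default_config()]).
#' @return data.frame of spindle events with columns `band`, `t_onset_s`,
#'   `t_offset_s`, `duration_s`, `peak_envelope_uv`, `t_peak_env_s`,
#'   `range_uv`, `stage`.
#' @export
detect_spindles <- function(recording, hyp, band = c("late_fast", "early_fast"),
                            config = swa_default_config()) {
  band <- match.arg(band)
  check_paired(recording, hyp)
  fs <- recording$sampling_rate_hz
  sp <- config$spindle
  det <- sliding_detrend(recording$samples, fs, config$detrend$window_s)
  art <- high_amplitude_mask(det, fs, config$artifact$threshold_uv,
                             config$detrend$window_s)
  mask <- combine_masks(art, hyp, fs, config$sw$keep_stages)
  analyzable <- !mask_excluded(mask)
  filt <- bandpass_spindle(det, fs, config$filters[[band]]$band,
                           config$filters[[band]]$order)
  env <- upper_envelope(filt)
  if (!any(analyzable)) return(empty_spindle_df())
  thr <- spindle_threshold(env, analyzable, fs,
                           sp$rms_window_s, sp$threshold_quantile)

  above <- env > thr & analyzable
  if (!any(above)) return(empty_spindle_df())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  # bridge sub-threshold gaps shorter than merge_gap_s (analyzable gaps only,
  # so segments never merge across a masked region)
  gap_n <- sp$merge_gap_s * fs
  if (nrow(seg) > 1L) {
    keep <- seg[1L, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      k <- nrow(keep)
      gap <- (seg[i, 1L] - keep[k, 2L] - 1L)
      if (gap < gap_n && all(analyzable[(keep[k, 2L] + 1L):(seg[i, 1L] - 1L)]))
        keep[k, 2L] <- seg[i, 2L]
      else keep <- rbind(keep, seg[i, , drop = FALSE])
    }
    seg <- keep
  }
  dur <- (seg[, 2L] - seg[, 1L] + 1L) / fs
  seg <- seg[dur >= sp$min_dur_s & dur <= sp$max_dur_s, , drop = FALSE]
  if (!nrow(seg)) return(empty_spindle_df())

  peak_env <- mean_env <- t_peak <- rng <- numeric(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    idx <- seg[i, 1L]:seg[i, 2L]
    pe <- which.max(env[idx])
    peak_env[i] <- env[idx][pe]
    mean_env[i] <- mean(env[idx])
    t_peak[i] <- (idx[pe] - 1) / fs
    rng[i] <- max(filt[idx]) - min(filt[idx])
  }
  ev <- data.frame(
    band = band,
    t_onset_s = (seg[, 1L] - 1) / fs,
    t_offset_s = (seg[, 2L] - 1) / fs,
    duration_s = (seg[, 2L] - seg[, 1L] + 1L) / fs,
    peak_envelope_uv = peak_env,
    mean_envelope_uv = mean_env,
    t_peak_env_s = t_peak,
    range_uv = rng
  )
  ev <- ev[ev$range_uv <= sp$max_range_uv, , drop = FALSE]
  ev <- reject_envelope_outliers(
    ev, sp$reject_sd,
    if (identical(sp$reject_on, "mean")) "mean_envelope_uv" else "peak_envelope_uv")
  ev$stage <- stage_at(hyp, ev$t_onset_s)
  rownames(ev) <- NULL
  ev
}

#' Reject envelope-amplitude outlier events
#'
#' Drops events whose peak envelope deviates more than `reject_sd` standard
#' deviations from the event-population mean (mean and SD computed once over
#' the input population, no iterative re-rejection).
#'
#' @param events data.frame with a `peak_envelope_uv` (and optionally
#'   `mean_envelope_uv`) column.
#' @param reject_sd Rejection threshold in standard deviations.
#' @param stat_col Envelope statistic used for the gate: peak (default) or
#'   per-event mean.
#' @return The retained subset of `events`.
#' @export
reject_envelope_outliers <- function(events, reject_sd = 8,
                                     stat_col = c("peak_envelope_uv",
                                                  "mean_envelope_uv")) {
  stat_col <- match.arg(stat_col)
  if (NROW(events) < 2L) return(events)
  stat <- events[[stat_col]]
  m <- mean(stat); s <- sd(stat)
  if (!is.finite(s) || s == 0) return(events)
  events[abs(stat - m) <= reject_sd * s, , drop = FALSE]
}

empty_spindle_df <- function() {
  data.frame(band = character(0), t_onset_s = numeric(0),
             t_offset_s = numeric(0), duration_s = numeric(0),
             peak_envelope_uv = numeric(0), t_peak_env_s = numeric(0),
             range_uv = numeric(0), stage = character(0))
}
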