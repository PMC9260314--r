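#' Default analysis configuration
#'
#' All tunable parameters of the detection and composition pipeline with their
#' default values. The defaults reproduce the reference methodology: a 3 s
#' sliding detrend, a 900 uV artifact ceiling, a zero-phase 6th-order
#' Butterworth 0.16-4 Hz slow band, zero-phase 3rd-order Butterworth spindle
#' bands at 10-13.5 Hz (late-fast) and 14.5-18 Hz (early-fast) with the
#' 13.5-14.5 Hz band excluded, a 75th-percentile moving-RMS spindle threshold
#' with a 0.5-3.0 s event window and 40 uV range gate, and the 0.2-1.5 s
#' post-trough coupling window.
#'
#' @return Nested named list of configuration values.
#' @export
swa_default_config <- function() {
  list(
    detrend = list(window_s = 3.0),
    artifact = list(threshold_uv = 900),
    filters = list(
      slow = list(order = 6L, band = c(0.16, 4)),
      late_fast = list(order = 3L, band = c(10, 13.5)),
      early_fast = list(order = 3L, band = c(14.5, 18))
    ),
    sw = list(
      min_dur_s = 0.25,       # full-wave duration bounds <=> 0.4-4 Hz
      max_dur_s = 2.5,
      max_amp_uv = 200,       # +/- ceiling on trough and peak
      reject_sd = 4,
      keep_stages = c("N2", "N3")
    ),
    spindle = list(
      rms_window_s = 0.5,     # moving-RMS window for the threshold series
      threshold_quantile = 0.75,
      min_dur_s = 0.5,
      max_dur_s = 3.0,
      max_range_uv = 40,
      merge_gap_s = 0.1,
      reject_sd = 8,
      reject_on = "peak"      # or "mean": envelope statistic for the 8-SD gate
    ),
    coupling = list(
      window_s = c(0.2, 1.5), # post-trough window; lower edge is the buffer
      reference = "onset"     # or "peak": spindle time used against the trough
    ),
    tfr = list(
      freq_lo_hz = 4, freq_hi_hz = 20, freq_step_hz = 0.25,
      half_width_s = 2.5, n_cycles = 8,
      max_events = 250        # events subsampled per night for TFR averaging
    ),
    rois = list(
      # Placeholder rectangles mirroring the detection bands and coupling
      # window; set explicitly for any replication of published ROI power.
      late_fast = list(f_lo_hz = 10, f_hi_hz = 13.5, t_lo_s = 0.2, t_hi_s = 1.5),
      early_fast = list(f_lo_hz = 14.5, f_hi_hz = 18, t_lo_s = 0.2, t_hi_s = 1.5)
    ),
    composition = list(
      bin_width_s = 120,
      n_norm_bins = 100L,
      high_lf_threshold_pct = 80
    ),
    stages = list(
      # Stage-token mapping tables per hypnogram dialect. Kept in config so
      # site-specific codes can be supplied without code changes.
      dreams = c("5" = "W", "4" = "REM", "3" = "N1", "2" = "N2",
                 "1" = "N3", "0" = "N3", "-1" = "UNSCORABLE",
                 "-2" = "UNSCORABLE", "-3" = "UNSCORABLE"),
      nsrr_xml = c("0" = "W", "1" = "N1", "2" = "N2", "3" = "N3",
                   "4" = "N3", "5" = "REM"),
      plain_text = c("W" = "W", "N1" = "N1", "N2" = "N2", "N3" = "N3",
                     "REM" = "REM", "R" = "REM", "UNSCORABLE" = "UNSCORABLE")
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over [swa_default_config()];
#' values present in the file override defaults, everything else keeps its
#' default.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested named list of configuration values.
#' @export
swa_load_config <- function(path = NULL) {
  cfg <- swa_default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

# Stable hash of a configuration for run provenance.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
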