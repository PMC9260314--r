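#' Classify slow-wave/spindle coupling
#'
#' A slow wave is coupled when at least one spindle's reference time (onset by
#' default) falls inside the post-trough window `[trough + 0.2, trough + 1.5]`
#' seconds; the 0.2 s lower edge buffers against pre-trough slow-spindle
#' activity. Classification rules:
#' * spindles of exactly one band qualifying: the slow wave is coupled to the
#'   earliest qualifying spindle of that band (`late_fast` -> `LF_SW`,
#'   `early_fast` -> `EF_SW`);
#' * spindles of both bands qualifying: the slow wave is left unclassified
#'   (ambiguous) rather than double-counted, preserving the partition
#'   `LF + EF + unclassified = total`;
#' * no qualifying spindle: unclassified.
#' Each spindle is consumed by at most one slow wave; when one spindle falls
#' in the windows of several slow waves the earliest trough claims it.
#'
#' @param slow_waves data.frame from [detect_slow_waves()], time-sorted.
#' @param late_fast,early_fast data.frames from [detect_spindles()],
#'   time-sorted on the same recording timeline (channels may differ).
#' @param window_s Post-trough window `c(lo, hi)` in seconds.
#' @param reference `"onset"` or `"peak"`: spindle time compared to the
#'   trough.
#' @param sw_channel,spindle_channel Channel labels recorded on each coupled
#'   event.
#' @return List with `coupled` (data.frame: `subtype`, `lag_s`, slow-wave
#'   fields prefixed `sw_`, spindle fields prefixed `sp_`, channel labels) and
#'   `unclassified` (the remaining slow-wave rows).
#' @export
classify_coupling <- function(slow_waves, late_fast, early_fast,
                              window_s = c(0.2, 1.5), reference = "onset",
                              sw_channel = NA_character_,
                              spindle_channel = NA_character_) {
  if (NROW(slow_waves) && is.unsorted(slow_waves$t_trough_s))
    stop("slow_waves must be sorted by t_trough_s")
  ref_col <- if (identical(reference, "peak")) "t_peak_env_s" else "t_onset_s"
  for (sp in list(late_fast, early_fast)) {
    if (NROW(sp) && is.unsorted(sp[[ref_col]]))
      stop("spindle events must be sorted by their reference time")
  }
  lf_t <- if (NROW(late_fast)) late_fast[[ref_col]] else numeric(0)
  ef_t <- if (NROW(early_fast)) early_fast[[ref_col]] else numeric(0)
  lf_free <- rep(TRUE, length(lf_t))
  ef_free <- rep(TRUE, length(ef_t))

  n <- NROW(slow_waves)
  subtype <- rep(NA_character_, n)
  lag <- rep(NA_real_, n)
  sp_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tt <- slow_waves$t_trough_s[i]
    lo <- tt + window_s[1L]; hi <- tt + window_s[2L]
    li <- which(lf_free & lf_t >= lo & lf_t <= hi)
    ei <- which(ef_free & ef_t >= lo & ef_t <= hi)
    if (length(li) && length(ei)) next         # ambiguous -> unclassified
    if (length(li)) {
      j <- li[which.min(lf_t[li])]
      lf_free[j] <- FALSE
      subtype[i] <- "LF_SW"; lag[i] <- lf_t[j] - tt; sp_idx[i] <- j
    } else if (length(ei)) {
      j <- ei[which.min(ef_t[ei])]
      ef_free[j] <- FALSE
      subtype[i] <- "EF_SW"; lag[i] <- ef_t[j] - tt; sp_idx[i] <- j
    }
  }

  is_coupled <- !is.na(subtype)
  coupled <- do.call(rbind, lapply(which(is_coupled), function(i) {
    sp <- if (subtype[i] == "LF_SW") late_fast[sp_idx[i], , drop = FALSE]
    else early_fast[sp_idx[i], , drop = FALSE]
    data.frame(
      subtype = subtype[i],
      lag_s = lag[i],
      sw_t_trough_s = slow_waves$t_trough_s[i],
      sw_trough_uv = slow_waves$trough_uv[i],
      sw_peak_uv = slow_waves$peak_uv[i],
      sw_stage = slow_waves$stage[i],
      sp_band = sp$band,
      sp_t_onset_s = sp$t_onset_s,
      sp_duration_s = sp$duration_s,
      sp_peak_envelope_uv = sp$peak_envelope_uv,
      sw_channel = sw_channel,
      spindle_channel = spindle_channel
    )
  }))
  if (is.null(coupled)) coupled <- empty_coupled_df()
  rownames(coupled) <- NULL
  list(coupled = coupled,
       unclassified = slow_waves[!is_coupled, , drop = FALSE])
}

empty_coupled_df <- function() {
  data.frame(subtype = character(0), lag_s = numeric(0),
             sw_t_trough_s = numeric(0), sw_trough_uv = numeric(0),
             sw_peak_uv = numeric(0), sw_stage = character(0),
             sp_band = character(0), sp_t_onset_s = numeric(0),
             sp_duration_s = numeric(0), sp_peak_envelope_uv = numeric(0),
             sw_channel = character(0), spindle_channel = character(0))
}
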