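#' Find half-wave-pair slow-wave candidates by zero-crossing analysis
#'
#' A candidate is a negative half-wave immediately followed by a positive
#' half-wave, delimited by three consecutive zero crossings of the slow-band
#' filtered signal, whose full-wave duration lies in `[min_dur_s, max_dur_s]`
#' (0.25-2.5 s by default, i.e. a 0.4-4 Hz full-wave frequency). Candidates
#' that touch an excluded mask range are dropped, as is a trailing incomplete
#' half-wave at a mask or signal boundary.
#'
#' @param filtered Slow-band filtered signal (from [bandpass_slow()]).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param mask Optional [sample_mask()]; `NULL` means all samples analyzable.
#' @param min_dur_s,max_dur_s Full-wave duration bounds in seconds.
#' @return data.frame of candidates with columns `t_down_zc_s`, `t_trough_s`,
#'   `trough_uv`, `t_up_zc_s`, `t_peak_s`, `peak_uv`, `t_end_zc_s`,
#'   `duration_s`. Times are seconds from recording start (sample 1 at 0 s).
#' @export
find_half_wave_pairs <- function(filtered, sampling_rate_hz, mask = NULL,
                                 min_dur_s = 0.25, max_dur_s = 2.5) {
  n <- length(filtered)
  fs <- sampling_rate_hz
  neg <- filtered < 0
  # crossing "at" index i: sign differs between samples i and i+1; the
  # crossing sample index is the first sample on the new side (i + 1).
  flips <- which(neg[-1L] != neg[-n]) + 1L
  if (length(flips) < 3L) return(empty_sw_df())
  down <- flips[neg[flips]]       # entering the negative half-wave
  up <- flips[!neg[flips]]        # entering the positive half-wave
  if (length(down) < 2L || !length(up)) return(empty_sw_df())

  excl <- if (is.null(mask)) rep(FALSE, n) else mask_excluded(mask)
  ecum <- cumsum(excl)

  rows <- vector("list", length(down) - 1L)
  k <- 0L
  for (i in seq_len(length(down) - 1L)) {
    d <- down[i]; e <- down[i + 1L]
    j <- findInterval(d, up) + 1L
    if (j > length(up)) break
    u <- up[j]
    if (u >= e) next                        # no positive half-wave between
    dur <- (e - d) / fs
    if (dur < min_dur_s || dur > max_dur_s) next
    if (ecum[e] - ecum[d - 1L] > 0L) next   # touches an excluded range
    neg_seg <- d:(u - 1L)
    pos_seg <- u:(e - 1L)
    ti <- neg_seg[which.min(filtered[neg_seg])]
    pi_ <- pos_seg[which.max(filtered[pos_seg])]
    trough <- filtered[ti]; peak <- filtered[pi_]
    if (!(trough < 0 && peak > 0)) next
    k <- k + 1L
    rows[[k]] <- c(d, ti, trough, u, pi_, peak, e, dur)
  }
  if (!k) return(empty_sw_df())
  m <- do.call(rbind, rows[seq_len(k)])
  data.frame(
    t_down_zc_s = (m[, 1L] - 1) / fs,
    t_trough_s = (m[, 2L] - 1) / fs,
    trough_uv = m[, 3L],
    t_up_zc_s = (m[, 4L] - 1) / fs,
    t_peak_s = (m[, 5L] - 1) / fs,
    peak_uv = m[, 6L],
    t_end_zc_s = (m[, 7L] - 1) / fs,
    duration_s = m[, 8L]
  )
}

empty_sw_df <- function() {
  data.frame(t_down_zc_s = numeric(0), t_trough_s = numeric(0),
             trough_uv = numeric(0), t_up_zc_s = numeric(0),
             t_peak_s = numeric(0), peak_uv = numeric(0),
             t_end_zc_s = numeric(0), duration_s = numeric(0))
}

#' Amplitude selection of slow-wave candidates
#'
#' Three sequential gates, in the order of the underlying methodology:
#' 1. the top-50% rule: only candidates with `|trough| >= median(|trough|)`
#'    AND `peak >= median(peak)`, both medians taken over all candidates, are
#'    selected. The median boundary is inclusive, so ties at the median
#'    survive (and slightly more than 50% may be retained);
#' 2. the `+/- max_amp_uv` ceiling (strict `>` comparison) on trough and
#'    peak, reducing misidentification of non-slow-wave events;
#' 3. a further reduction rejecting selected candidates whose trough or peak
#'    deviates more than `reject_sd` standard deviations from the respective
#'    mean of the selected population (computed once, separately for troughs
#'    and peaks, no iterative re-rejection).
#'
#' @param candidates data.frame from [find_half_wave_pairs()].
#' @param max_amp_uv Amplitude ceiling in microvolts.
#' @param reject_sd Outlier rejection threshold in standard deviations.
#' @return The retained subset of `candidates`.
#' @export
amplitude_select <- function(candidates, max_amp_uv = 200, reject_sd = 4) {
  if (!NROW(candidates)) stop("amplitude_select requires at least one candidate")
  x <- candidates[abs(candidates$trough_uv) >= median(abs(candidates$trough_uv)) &
                    candidates$peak_uv >= median(candidates$peak_uv), ,
                  drop = FALSE]
  if (!NROW(x)) return(x)
  x <- x[abs(x$trough_uv) <= max_amp_uv & abs(x$peak_uv) <= max_amp_uv, ,
         drop = FALSE]
  if (NROW(x) > 1L) {
    keep <- rep(TRUE, NROW(x))
    mt <- mean(x$trough_uv); st <- sd(x$trough_uv)
    if (is.finite(st) && st > 0)
      keep <- keep & abs(x$trough_uv - mt) <= reject_sd * st
    mp <- mean(x$peak_uv); sp <- sd(x$peak_uv)
    if (is.finite(sp) && sp > 0)
      keep <- keep & abs(x$peak_uv - mp) <= reject_sd * sp
    x <- x[keep, , drop = FALSE]
  }
  x
}

#' Detect slow waves in a recording
#'
#' Full slow-wave pipeline: sliding detrend, high-amplitude artifact mask,
#' stage restriction to N2/N3, zero-phase 0.16-4 Hz band-pass, zero-crossing
#' half-wave pairing, and amplitude selection. Events are sorted by trough
#' time and stamped with the stage of the epoch containing the trough (all
#' downstream timing is trough-locked).
#'
#' @param recording An [eeg_recording()].
#' @param hyp A paired [hypnogram()].
#' @param config Configuration list (see [swa_default_config()]).
#' @return data.frame of slow-wave events (columns of
#'   [find_half_wave_pairs()] plus `stage`).
#' @export
detect_slow_waves <- function(recording, hyp, config = swa_default_config()) {
  check_paired(recording, hyp)
  fs <- recording$sampling_rate_hz
  det <- sliding_detrend(recording$samples, fs, config$detrend$window_s)
  art <- high_amplitude_mask(det, fs, config$artifact$threshold_uv,
                             config$detrend$window_s)
  mask <- combine_masks(art, hyp, fs, config$sw$keep_stages)
  filt <- bandpass_slow(det, fs, config$filters$slow$band,
                        config$filters$slow$order)
  cand <- find_half_wave_pairs(filt, fs, mask,
                               config$sw$min_dur_s, config$sw$max_dur_s)
  if (!NROW(cand)) return(cbind(cand, stage = character(0)))
  ev <- amplitude_select(cand, config$sw$max_amp_uv, config$sw$reject_sd)
  ev$stage <- stage_at(hyp, ev$t_trough_s)
  ev <- ev[ev$stage %in% config$sw$keep_stages, , drop = FALSE]
  ev <- ev[order(ev$t_trough_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
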