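# SWA composition summaries: how the mix of late-fast vs early-fast coupled
# slow waves changes over the night and between sleep stages.

#' Time-binned SWA composition
#'
#' Left-closed, right-open bins anchored at t = 0 over wall-clock recording
#' time (2 min by default). A coupled event belongs to the bin containing its
#' slow-wave trough; an event exactly on a boundary goes to the right bin.
#' Empty bins carry an undefined (`NA`) percentage, not 0%, so they can never
#' satisfy a composition threshold.
#'
#' @param coupled data.frame from [classify_coupling()].
#' @param recording_duration_s Recording duration in seconds.
#' @param bin_width_s Bin width in seconds.
#' @return data.frame with `t_start_s`, `t_end_s`, `n_lf`, `n_ef`, `pct_lf`.
#' @export
bin_composition <- function(coupled, recording_duration_s, bin_width_s = 120) {
  if (bin_width_s <= 0) stop("bin width must be positive")
  n_bins <- max(1L, as.integer(ceiling(recording_duration_s / bin_width_s)))
  starts <- (seq_len(n_bins) - 1L) * bin_width_s
  out <- data.frame(t_start_s = starts,
                    t_end_s = pmin(starts + bin_width_s, recording_duration_s),
                    n_lf = 0L, n_ef = 0L)
  if (NROW(coupled)) {
    bin <- floor(coupled$sw_t_trough_s / bin_width_s) + 1L
    bin <- pmin(pmax(bin, 1L), n_bins)
    lf <- tabulate(bin[coupled$subtype == "LF_SW"], nbins = n_bins)
    ef <- tabulate(bin[coupled$subtype == "EF_SW"], nbins = n_bins)
    out$n_lf <- lf; out$n_ef <- ef
  }
  tot <- out$n_lf + out$n_ef
  out$pct_lf <- ifelse(tot > 0, 100 * out$n_lf / tot, NA_real_)
  out
}

#' Stage-specific SWA composition
#'
#' Each coupled event is assigned to the stage of the epoch containing its
#' slow-wave trough; events falling outside the kept stages (which should not
#' occur for a correctly masked detection run) are excluded with a warning.
#'
#' @param coupled data.frame from [classify_coupling()].
#' @param hyp A [hypnogram()] on the same timeline.
#' @param stages Stages to summarize.
#' @return data.frame with one row per stage: `stage`, `n_lf`, `n_ef`,
#'   `pct_lf` (`NA` when the stage has no coupled events).
#' @export
stage_percentages <- function(coupled, hyp, stages = c("N2", "N3")) {
  st <- if (NROW(coupled)) stage_at(hyp, coupled$sw_t_trough_s) else character(0)
  outside <- NROW(coupled) && any(!st %in% stages)
  if (outside) {
    warning(sum(!st %in% stages),
            " coupled event(s) outside the kept stages were excluded")
  }
  out <- data.frame(stage = stages, n_lf = 0L, n_ef = 0L)
  for (i in seq_along(stages)) {
    sel <- st == stages[i]
    out$n_lf[i] <- sum(sel & coupled$subtype == "LF_SW")
    out$n_ef[i] <- sum(sel & coupled$subtype == "EF_SW")
  }
  tot <- out$n_lf + out$n_ef
  out$pct_lf <- ifelse(tot > 0, 100 * out$n_lf / tot, NA_real_)
  out
}

#' SWA composition over normalized NREM time
#'
#' The night's N2 and N3 epochs are concatenated in temporal order into a
#' normalized time axis of unit length, which is divided into `n_bins`
#' equal-duration bins (so with 100 bins each bin spans 1% of total NREM
#' time). Coupled events are placed by the normalized position of their
#' slow-wave trough; events outside N2/N3 are dropped. Bin times on the
#' output are NREM-seconds (concatenated-axis seconds), not wall-clock.
#'
#' @param coupled data.frame from [classify_coupling()].
#' @param hyp A [hypnogram()] on the same timeline.
#' @param n_bins Number of normalized bins.
#' @param stages Stages forming the normalized axis.
#' @return data.frame as in [bin_composition()].
#' @export
normalized_nrem_bins <- function(coupled, hyp, n_bins = 100L,
                                 stages = c("N2", "N3")) {
  nrem_ep <- which(hyp$stages %in% stages)
  if (!length(nrem_ep)) stop("hypnogram contains no NREM time")
  ep_s <- hyp$epoch_seconds
  total <- length(nrem_ep) * ep_s
  # cumulative NREM seconds before each epoch of the night
  before <- cumsum(hyp$stages %in% stages) * ep_s
  width <- total / n_bins
  out <- data.frame(t_start_s = (seq_len(n_bins) - 1L) * width,
                    t_end_s = seq_len(n_bins) * width,
                    n_lf = 0L, n_ef = 0L)
  if (NROW(coupled)) {
    ep <- floor(coupled$sw_t_trough_s / ep_s) + 1L
    ok <- ep >= 1L & ep <= length(hyp$stages) & hyp$stages[pmin(ep, length(hyp$stages))] %in% stages
    if (any(ok)) {
      offset <- coupled$sw_t_trough_s[ok] - (ep[ok] - 1L) * ep_s
      pos <- (before[ep[ok]] - ep_s + offset) / total
      bin <- pmin(pmax(floor(pos * n_bins) + 1L, 1L), n_bins)
      out$n_lf <- tabulate(bin[coupled$subtype[ok] == "LF_SW"], nbins = n_bins)
      out$n_ef <- tabulate(bin[coupled$subtype[ok] == "EF_SW"], nbins = n_bins)
    }
  }
  tot <- out$n_lf + out$n_ef
  out$pct_lf <- ifelse(tot > 0, 100 * out$n_lf / tot, NA_real_)
  out
}

#' Count bins dominated by late-fast coupled events
#'
#' Number of bins whose defined late-fast percentage is greater than or equal
#' to the threshold ("80% or more"); bins with no coupled events have an
#' undefined percentage and never count.
#'
#' @param bins data.frame from [bin_composition()] or
#'   [normalized_nrem_bins()].
#' @param threshold_pct Composition threshold in percent.
#' @return Integer count.
#' @export
high_lf_bin_count <- function(bins, threshold_pct = 80) {
  sum(!is.na(bins$pct_lf) & bins$pct_lf >= threshold_pct)
}
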