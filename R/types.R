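#' EEG recording container
#'
#' A single referenced EEG channel held in memory. All amplitudes inside the
#' package are microvolts; unit conversion happens exactly once, when a file
#' is read.
#'
#' @param samples Numeric vector of samples in microvolts.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier.
#' @param channel_label Channel name, e.g. `"FP1"`, `"CZ"`, `"C3"`.
#' @param reference_label Reference electrode name (e.g. `"A2"`) or `NA` when
#'   the stored trace is already referenced.
#' @param start_time_s Time of the first sample; 0 at recording start.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate_hz, subject_id = "unknown",
                          channel_label = "EEG", reference_label = NA_character_,
                          start_time_s = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  structure(
    list(subject_id = as.character(subject_id),
         channel_label = as.character(channel_label),
         reference_label = as.character(reference_label),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         samples = as.numeric(samples),
         start_time_s = as.numeric(start_time_s)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate_hz
  cat(sprintf("<eeg_recording> %s %s%s: %d samples @ %g Hz (%.1f min)\n",
              x$subject_id, x$channel_label,
              if (is.na(x$reference_label)) "" else paste0("-", x$reference_label),
              length(x$samples), x$sampling_rate_hz, dur / 60))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An [eeg_recording()].
#' @return Duration in seconds.
#' @export
recording_duration_s <- function(recording) {
  length(recording$samples) / recording$sampling_rate_hz
}

# Canonical sleep stage labels.
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM", "UNSCORABLE")

#' Hypnogram container
#'
#' Fixed-length-epoch sleep stage labels. Stage tokens outside the canonical
#' set `W, N1, N2, N3, REM, UNSCORABLE` are rejected; file readers map unknown
#' tokens to `UNSCORABLE` before construction.
#'
#' @param stages Character vector of stage labels.
#' @param epoch_seconds Epoch length in seconds (> 0), 30 by convention.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_seconds = 30) {
  stages <- as.character(stages)
  if (!length(stages)) stop("hypnogram has no epochs")
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage labels: ", paste(bad, collapse = ", "))
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L || epoch_seconds <= 0)
    stop("epoch_seconds must be a single positive number")
  structure(list(epoch_seconds = as.numeric(epoch_seconds), stages = stages),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s (%.1f min)\n",
              length(x$stages), x$epoch_seconds,
              length(x$stages) * x$epoch_seconds / 60))
  print(table(factor(x$stages, levels = STAGE_LEVELS)))
  invisible(x)
}

#' Stage label at a time point
#'
#' @param hyp A [hypnogram()].
#' @param t_s Time(s) in seconds from recording start.
#' @return Character vector of stage labels; times past the scored portion
#'   return `"UNSCORABLE"`.
#' @export
stage_at <- function(hyp, t_s) {
  idx <- floor(t_s / hyp$epoch_seconds) + 1L
  out <- rep("UNSCORABLE", length(idx))
  ok <- idx >= 1L & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

#' Check that a hypnogram and a recording describe the same night
#'
#' Enforced at pairing time (not at read time): the scored duration must lie
#' within one epoch of the recording duration.
#'
#' @param recording An [eeg_recording()].
#' @param hyp A [hypnogram()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_paired <- function(recording, hyp) {
  dur <- recording_duration_s(recording)
  scored <- length(hyp$stages) * hyp$epoch_seconds
  if (abs(dur - scored) > hyp$epoch_seconds)
    stop(sprintf("hypnogram (%g s) and recording (%g s) differ by more than one epoch",
                 scored, dur))
  invisible(TRUE)
}

#' Sample exclusion mask
#'
#' Half-open, 0-based sample index ranges marked as excluded from analysis.
#' Ranges are normalized (sorted, merged, clipped) on construction.
#'
#' @param length_n Number of samples in the masked recording.
#' @param excluded Two-column matrix of half-open `[start, end)` 0-based
#'   ranges, or `NULL` for an empty mask.
#' @return An object of class `sample_mask`.
#' @export
sample_mask <- function(length_n, excluded = NULL) {
  length_n <- as.integer(length_n)
  stopifnot(length_n >= 0L)
  if (is.null(excluded) || NROW(excluded) == 0L) {
    excluded <- matrix(numeric(0), ncol = 2L,
                       dimnames = list(NULL, c("start", "end")))
  } else {
    excluded <- matrix(as.numeric(excluded), ncol = 2L)
    colnames(excluded) <- c("start", "end")
    excluded[, 1L] <- pmax(excluded[, 1L], 0)
    excluded[, 2L] <- pmin(excluded[, 2L], length_n)
    excluded <- excluded[excluded[, 2L] > excluded[, 1L], , drop = FALSE]
    if (nrow(excluded) > 1L) {
      excluded <- excluded[order(excluded[, 1L]), , drop = FALSE]
      merged <- excluded[1L, , drop = FALSE]
      for (i in seq_len(nrow(excluded))[-1L]) {
        k <- nrow(merged)
        if (excluded[i, 1L] <= merged[k, 2L])
          merged[k, 2L] <- max(merged[k, 2L], excluded[i, 2L])
        else merged <- rbind(merged, excluded[i, , drop = FALSE])
      }
      excluded <- merged
    }
  }
  structure(list(length = length_n, excluded = excluded), class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  ns <- if (nrow(x$excluded)) sum(x$excluded[, 2L] - x$excluded[, 1L]) else 0
  cat(sprintf("<sample_mask> %d samples, %d excluded range(s), %.0f samples excluded\n",
              x$length, nrow(x$excluded), ns))
  invisible(x)
}

#' Logical view of a sample mask
#'
#' @param mask A [sample_mask()].
#' @return Logical vector, `TRUE` where the sample is excluded.
#' @export
mask_excluded <- function(mask) {
  out <- rep(FALSE, mask$length)
  for (i in seq_len(nrow(mask$excluded))) {
    out[(mask$excluded[i, 1L] + 1L):mask$excluded[i, 2L]] <- TRUE
  }
  out
}

# Build a sample_mask from a logical excluded vector.
mask_from_logical <- function(excluded) {
  n <- length(excluded)
  if (!any(excluded)) return(sample_mask(n))
  r <- rle(excluded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  sample_mask(n, cbind(starts[r$values], ends[r$values]))
}
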