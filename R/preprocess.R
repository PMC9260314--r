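#' Sliding-window linear detrend
#'
#' Removes a per-window least-squares linear trend in consecutive,
#' non-overlapping windows (default 3 s); a shorter remainder at the end of
#' the signal is detrended as its own window. Within each full window the
#' output mean is zero and any linear ramp is removed, while oscillations
#' faster than the window survive essentially unchanged.
#'
#' @param x Signal in microvolts.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return Detrended signal, same length as `x`.
#' @export
sliding_detrend <- function(x, sampling_rate_hz, window_s = 3.0) {
  n <- length(x)
  w <- as.integer(round(window_s * sampling_rate_hz))
  if (w < 2L) stop("detrend window must span at least 2 samples")
  if (w > n) stop("detrend window longer than the signal")
  m <- n %/% w
  out <- numeric(n)
  if (m > 0L) {
    Y <- matrix(x[seq_len(m * w)], nrow = w)
    tc <- seq_len(w) - (w + 1) / 2
    stt <- sum(tc^2)
    slope <- colSums(Y * tc) / stt
    inter <- colMeans(Y)
    out[seq_len(m * w)] <- as.numeric(Y - outer(tc, slope) -
                                        rep(inter, each = w))
  }
  rem <- n - m * w
  if (rem >= 2L) {
    idx <- m * w + seq_len(rem)
    tc <- seq_len(rem) - (rem + 1) / 2
    slope <- sum(x[idx] * tc) / sum(tc^2)
    out[idx] <- x[idx] - mean(x[idx]) - tc * slope
  } else if (rem == 1L) {
    out[n] <- 0
  }
  out
}

#' High-amplitude artifact mask
#'
#' Marks every detrend window that contains a sample with `|x| > threshold`
#' (strictly greater) as excluded. The exclusion granularity is the detrend
#' window because the amplitude ceiling is defined on the sliding-detrended
#' signal.
#'
#' @param detrended Detrended signal in microvolts.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param threshold_uv Amplitude ceiling in microvolts.
#' @param window_s Window granularity in seconds (matches the detrend window).
#' @return A [sample_mask()] of excluded windows (empty on clean data).
#' @export
high_amplitude_mask <- function(detrended, sampling_rate_hz,
                                threshold_uv = 900, window_s = 3.0) {
  stopifnot(threshold_uv > 0)
  n <- length(detrended)
  w <- as.integer(round(window_s * sampling_rate_hz))
  bad <- which(abs(detrended) > threshold_uv)
  if (!length(bad)) return(sample_mask(n))
  win <- unique((bad - 1L) %/% w)
  ranges <- cbind(win * w, pmin((win + 1L) * w, n))
  sample_mask(n, ranges)
}

#' Combine the artifact mask with the hypnogram stage restriction
#'
#' A sample is analyzable iff it lies outside every artifact range and inside
#' an epoch whose stage is in `keep_stages` (N2 and N3 by default). Everything
#' else is excluded; no masked sample enters any downstream threshold
#' estimate.
#'
#' @param artifact A [sample_mask()] from [high_amplitude_mask()].
#' @param hyp A [hypnogram()] paired with the same recording.
#' @param sampling_rate_hz Sampling rate of the masked recording.
#' @param keep_stages Stages retained for analysis.
#' @return A [sample_mask()] whose excluded set is the union.
#' @export
combine_masks <- function(artifact, hyp, sampling_rate_hz,
                          keep_stages = c("N2", "N3")) {
  n <- artifact$length
  epoch_n <- hyp$epoch_seconds * sampling_rate_hz
  ep <- floor((seq_len(n) - 1L) / epoch_n) + 1L
  stage <- rep("UNSCORABLE", n)
  ok <- ep <= length(hyp$stages)
  stage[ok] <- hyp$stages[ep[ok]]
  excluded <- !(stage %in% keep_stages) | mask_excluded(artifact)
  mask_from_logical(excluded)
}
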