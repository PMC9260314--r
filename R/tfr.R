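# Peri-event Morlet time-frequency analysis. Maps are amplitude (not power)
# on a 4-20 Hz x 0.25 Hz grid around slow-wave troughs, normalized by the
# per-frequency mean of matched pre-event baselines.

#' Time-frequency map container
#'
#' @param values Matrix `[frequency, time]` of wavelet amplitudes.
#' @param freqs_hz Frequency axis in Hz.
#' @param times_s Time axis in seconds (trough-relative for peri-event maps).
#' @return Object of class `tfr_map`.
#' @export
tfr_map <- function(values, freqs_hz, times_s) {
  stopifnot(nrow(values) == length(freqs_hz), ncol(values) == length(times_s),
            all(is.finite(values)))
  structure(list(freqs_hz = freqs_hz, times_s = times_s, values = values),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %d freqs (%g-%g Hz) x %d times (%g to %g s)\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s), min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Extract 5-s peri-trough segments
#'
#' Each slow-wave trough is centered in a `2 * half_width_s` window of the
#' unfiltered signal (half-open on the right: a trough at 10 s with fs 200
#' yields samples covering `[7.5, 12.5)`). Events whose window would cross a
#' recording edge are dropped and counted.
#'
#' @param x Unfiltered signal in microvolts.
#' @param events Slow-wave events (needs `t_trough_s`).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param half_width_s Half window in seconds.
#' @return List: `segments` (matrix, one row per event), `kept` (indices into
#'   `events`), `n_dropped`.
#' @export
peri_event_segments <- function(x, events, sampling_rate_hz, half_width_s = 2.5) {
  fs <- sampling_rate_hz
  L <- as.integer(round(2 * half_width_s * fs))
  starts <- as.integer(round((events$t_trough_s - half_width_s) * fs)) + 1L
  ok <- starts >= 1L & (starts + L - 1L) <= length(x)
  segs <- if (any(ok))
    t(vapply(starts[ok], function(s) x[s:(s + L - 1L)], numeric(L)))
  else matrix(numeric(0), ncol = L)
  list(segments = segs, kept = which(ok), n_dropped = sum(!ok))
}

#' Extract matched pre-event baseline segments
#'
#' For each event the candidate baseline is the window of the same length
#' immediately preceding the event's peri-trough window. Candidates that run
#' off the start of the recording or that contain any slow-wave trough (from
#' `all_slow_waves`) are discarded.
#'
#' @param x Unfiltered signal in microvolts.
#' @param events Events to baseline (needs `t_trough_s`).
#' @param all_slow_waves Every detected slow wave on this channel (used for
#'   the contamination check).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param half_width_s Half window of the peri-event segment in seconds.
#' @return List: `segments`, `kept`, `n_dropped` as in
#'   [peri_event_segments()].
#' @export
baseline_segments <- function(x, events, all_slow_waves, sampling_rate_hz,
                              half_width_s = 2.5) {
  fs <- sampling_rate_hz
  L <- as.integer(round(2 * half_width_s * fs))
  # baseline covers [t - 3*half_width, t - half_width)
  b_lo <- events$t_trough_s - 3 * half_width_s
  b_hi <- events$t_trough_s - half_width_s
  starts <- as.integer(round(b_lo * fs)) + 1L
  troughs <- all_slow_waves$t_trough_s
  clean <- vapply(seq_len(NROW(events)), function(i) {
    !any(troughs >= b_lo[i] & troughs < b_hi[i])
  }, TRUE)
  ok <- starts >= 1L & (starts + L - 1L) <= length(x) & clean
  segs <- if (any(ok))
    t(vapply(starts[ok], function(s) x[s:(s + L - 1L)], numeric(L)))
  else matrix(numeric(0), ncol = L)
  list(segments = segs, kept = which(ok), n_dropped = sum(!ok))
}

# Complex Morlet kernels for a frequency axis; support +/- 4 sigma_t.
morlet_kernels <- function(freqs_hz, sampling_rate_hz, n_cycles) {
  lapply(freqs_hz, function(f) {
    sigma <- n_cycles / (2 * pi * f)
    half <- ceiling(4 * sigma * sampling_rate_hz)
    t <- (-half:half) / sampling_rate_hz
    g <- exp(-t^2 / (2 * sigma^2))
    list(k = g * exp(2i * pi * f * t), scale = 2 / sum(g),
         half = as.integer(half))
  })
}

#' Morlet wavelet transform of a peri-event segment
#'
#' Complex Morlet wavelets (default 8 cycles) on a 4-20 Hz axis in 0.25 Hz
#' steps (65 frequencies), applied to the unfiltered segment. Values are
#' amplitude, scaled so a unit-amplitude sinusoid at an axis frequency maps
#' to 1. Edge effects are controlled by reflecting the segment at both ends
#' before convolution.
#'
#' @param segment Numeric segment (one row of [peri_event_segments()]).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_cycles Wavelet width in cycles.
#' @param freqs_hz Frequency axis.
#' @param times_s Optional time axis to stamp on the result; defaults to
#'   seconds from segment start.
#' @return A [tfr_map()] of raw amplitudes.
#' @export
morlet_tfr <- function(segment, sampling_rate_hz, n_cycles = 8,
                       freqs_hz = seq(4, 20, by = 0.25), times_s = NULL) {
  fs <- sampling_rate_hz
  if (max(freqs_hz) >= fs / 2) stop("sampling rate too low for the frequency axis")
  n <- length(segment)
  kerns <- morlet_kernels(freqs_hz, fs, n_cycles)
  maxh <- max(vapply(kerns, function(k) k$half, integer(1)))
  pad <- min(n - 1L, maxh)
  xp <- c(2 * segment[1L] - segment[seq(pad + 1L, 2L)], segment,
          2 * segment[n] - segment[seq(n - 1L, n - pad)])
  np <- length(xp)
  nfft <- 2^ceiling(log2(np + 2L * maxh + 1L))
  X <- fft(c(xp, numeric(nfft - np)))
  vals <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(kerns)) {
    kk <- kerns[[i]]
    K <- fft(c(kk$k, complex(real = numeric(nfft - length(kk$k)))))
    y <- fft(X * K, inverse = TRUE) / nfft
    # linear convolution: sample j of xp aligns at offset j + half
    center <- kk$half + pad + seq_len(n)
    vals[i, ] <- Mod(y[center]) * kk$scale
  }
  if (is.null(times_s)) times_s <- (seq_len(n) - 1) / fs
  tfr_map(vals, freqs_hz, times_s)
}

#' Baseline-normalized average time-frequency map
#'
#' The event maps are averaged cell-wise; each frequency row is then divided
#' by the mean of the baseline maps over both baselines and time at that
#' frequency. Identical event and baseline maps therefore normalize to 1
#' everywhere, and a global amplitude rescaling applied to both inputs
#' cancels.
#'
#' @param event_maps List of [tfr_map()]s around events.
#' @param baseline_maps List of [tfr_map()]s of matched baselines.
#' @return A [tfr_map()] of normalized amplitude.
#' @export
normalize_and_average <- function(event_maps, baseline_maps) {
  if (!length(event_maps) || !length(baseline_maps))
    stop("need at least one event map and one baseline map")
  mean_ev <- Reduce(`+`, lapply(event_maps, `[[`, "values")) / length(event_maps)
  base_f <- rowMeans(Reduce(`+`, lapply(baseline_maps, `[[`, "values"))) /
    length(baseline_maps)
  if (any(base_f == 0)) stop("zero baseline mean at some frequency")
  tfr_map(mean_ev / base_f, event_maps[[1L]]$freqs_hz, event_maps[[1L]]$times_s)
}

#' Mean map value inside a frequency-time region of interest
#'
#' @param map A [tfr_map()].
#' @param roi List with `f_lo_hz`, `f_hi_hz`, `t_lo_s`, `t_hi_s` (inclusive
#'   bounds).
#' @return Scalar mean over all grid cells inside the ROI.
#' @export
roi_power <- function(map, roi) {
  fi <- map$freqs_hz >= roi$f_lo_hz & map$freqs_hz <= roi$f_hi_hz
  ti <- map$times_s >= roi$t_lo_s & map$times_s <= roi$t_hi_s
  if (!any(fi) || !any(ti)) stop("ROI lies outside the map grid")
  mean(map$values[fi, ti])
}
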