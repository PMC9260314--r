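# Butterworth filters designed as cascaded second-order sections (biquads).
# Transfer-function (b, a) forms of high-order band-pass designs with a
# 0.16 Hz lower edge are numerically unstable in double precision at sleep-EEG
# sampling rates, so the design is done analytically: analog Butterworth
# prototype poles, low/high/band transformation in the s-domain, then a
# bilinear transform applied per section.

# Analog prototype poles for Butterworth order n (left half-plane, |p| = 1).
butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Bilinear transform of an analog biquad num = (b2 s^2 + b1 s + b0),
# den = (s^2 + a1 s + a0) at sampling rate fs. Returns list(b, a) in z^-1.
bilinear_biquad <- function(b2, b1, b0, a1, a0, fs) {
  K <- 2 * fs
  d0 <- K^2 + a1 * K + a0
  b <- c(b2 * K^2 + b1 * K + b0,
         -2 * b2 * K^2 + 2 * b0,
         b2 * K^2 - b1 * K + b0) / d0
  a <- c(1,
         (-2 * K^2 + 2 * a0) / d0,
         (K^2 - a1 * K + a0) / d0)
  list(b = b, a = a)
}

# Group complex s-plane poles into conjugate pairs; returns a list of
# (a1, a0) real biquad denominator coefficients (s^2 + a1 s + a0).
pair_conjugate_poles <- function(poles) {
  used <- rep(FALSE, length(poles))
  out <- list()
  for (i in seq_along(poles)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) < 1e-9 * max(1, abs(Re(p)))) {
      j <- which(!used & seq_along(poles) != i &
                   abs(Im(poles)) < 1e-9 * pmax(1, abs(Re(poles))))
      if (!length(j)) stop("unpaired real pole in filter design")
      q <- poles[j[1L]]
      used[c(i, j[1L])] <- TRUE
      out[[length(out) + 1L]] <- c(a1 = -Re(p + q), a0 = Re(p * q))
    } else {
      j <- which(!used & abs(poles - Conj(p)) < 1e-6 * abs(p))
      j <- setdiff(j, i)
      if (!length(j)) stop("unpaired complex pole in filter design")
      used[c(i, j[1L])] <- TRUE
      out[[length(out) + 1L]] <- c(a1 = -2 * Re(p), a0 = Mod(p)^2)
    }
  }
  out
}

# Evaluate the cascade's gain at digital frequency f_hz.
sos_gain <- function(sos, f_hz, fs) {
  z <- exp(-1i * 2 * pi * f_hz / fs)
  g <- 1 + 0i
  for (s in sos) {
    g <- g * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
      (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  }
  Mod(g)
}

#' Design a Butterworth filter in second-order sections
#'
#' @param order Filter order of the analog prototype; a band-pass of order `n`
#'   has `2n` poles.
#' @param band Corner frequency in Hz (scalar for `low`/`high`, length-2 for
#'   `pass`).
#' @param fs Sampling rate in Hz.
#' @param type `"low"`, `"high"`, or `"pass"`.
#' @return List of biquads, each `list(b, a)` in `z^-1`, with unit passband
#'   gain (at DC, Nyquist, or the geometric band centre respectively).
#' @export
butter_sos <- function(order, band, fs, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(band >= nyq) || any(band <= 0))
    stop("band edges must lie strictly inside (0, Nyquist)")
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  p <- butter_proto_poles(order)

  if (type == "low" || type == "high") {
    wc <- warp(band[1L])
    sp <- if (type == "low") p * wc else wc / p
    # odd order: one real pole -> first-order section
    real_i <- which(abs(Im(sp)) < 1e-9 * abs(sp))
    sos <- list()
    if (length(real_i)) {
      pr <- Re(sp[real_i[1L]])
      sp <- sp[-real_i[1L]]
      K <- 2 * fs
      if (type == "low") {
        b <- c(-pr, -pr) / (K - pr); a <- c(1, (-K - pr) / (K - pr))
      } else {
        b <- c(K, -K) / (K - pr); a <- c(1, (-K - pr) / (K - pr))
      }
      sos[[1L]] <- list(b = c(b, 0), a = c(a, 0))
    }
    for (sec in pair_conjugate_poles(sp)) {
      bq <- if (type == "low")
        bilinear_biquad(0, 0, sec["a0"], sec["a1"], sec["a0"], fs)
      else bilinear_biquad(1, 0, 0, sec["a1"], sec["a0"], fs)
      sos[[length(sos) + 1L]] <- bq
    }
    f_ref <- if (type == "low") 0 else nyq * 0.999
  } else {
    if (length(band) != 2L || band[2L] <= band[1L])
      stop("band-pass requires band = c(lo, hi) with lo < hi")
    w1 <- warp(band[1L]); w2 <- warp(band[2L])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    sp <- c(vapply(p, function(pp) {
      disc <- sqrt((pp * bw)^2 - 4 * w0^2 + 0i)
      (pp * bw + disc) / 2
    }, complex(1)),
    vapply(p, function(pp) {
      disc <- sqrt((pp * bw)^2 - 4 * w0^2 + 0i)
      (pp * bw - disc) / 2
    }, complex(1)))
    sos <- lapply(pair_conjugate_poles(sp), function(sec)
      bilinear_biquad(0, 1, 0, sec["a1"], sec["a0"], fs))
    f_ref <- sqrt(band[1L] * band[2L])
  }
  g <- sos_gain(sos, f_ref, fs)
  sos[[1L]]$b <- sos[[1L]]$b / g
  sos
}

# Apply one biquad (zero initial conditions) via the signal package's
# C-backed filter.
apply_section <- function(sec, x) {
  as.numeric(signal::filter(signal::Arma(b = sec$b, a = sec$a), x))
}

# Largest pole modulus across sections: governs transient decay and hence
# the reflection pad length for zero-phase filtering.
sos_max_pole <- function(sos) {
  mx <- 0
  for (s in sos) {
    r <- polyroot(rev(s$a[s$a != 0 | seq_along(s$a) == 1L]))
    if (length(r)) mx <- max(mx, Mod(r))
  }
  mx
}

#' Zero-phase filtering through second-order sections
#'
#' Forward-backward application with odd-reflection padding long enough for
#' each section's transient to decay; the padded region is discarded. The
#' magnitude response is therefore the squared Butterworth magnitude and the
#' phase response is identically zero.
#'
#' @param sos Sections from [butter_sos()].
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  rho <- min(sos_max_pole(sos), 1 - 1e-9)
  padlen <- min(n - 1L, as.integer(ceiling(6 / (1 - rho))) + 9L)
  if (padlen > 0L) {
    front <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
    back <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    xp <- c(front, x, back)
  } else xp <- x
  for (s in sos) xp <- apply_section(s, xp)
  xp <- rev(xp)
  for (s in sos) xp <- apply_section(s, xp)
  xp <- rev(xp)
  xp[padlen + seq_len(n)]
}

# cache filter designs within a session (keyed on order/band/fs/type)
.filter_cache <- new.env(parent = emptyenv())
cached_sos <- function(order, band, fs, type) {
  key <- paste(order, paste(band, collapse = "-"), fs, type, sep = "|")
  if (is.null(.filter_cache[[key]]))
    .filter_cache[[key]] <- butter_sos(order, band, fs, type)
  .filter_cache[[key]]
}

#' Slow-oscillation band-pass (0.16-4 Hz, zero phase)
#'
#' 6th-order Butterworth band-pass applied forward and backward. The cascade
#' of second-order sections keeps the 0.16 Hz edge numerically stable where a
#' single transfer-function realization is not.
#'
#' @param x Signal in microvolts.
#' @param sampling_rate_hz Sampling rate (> 8 Hz so 4 Hz is in-band).
#' @param band Band edges in Hz.
#' @param order Prototype order.
#' @return Filtered signal, same length.
#' @export
bandpass_slow <- function(x, sampling_rate_hz, band = c(0.16, 4), order = 6L) {
  if (sampling_rate_hz <= 2 * band[2L])
    stop("sampling rate too low for the slow band")
  sos <- cached_sos(order, band, sampling_rate_hz, "pass")
  sos_filtfilt(sos, x)
}

#' Spindle band-pass (zero phase)
#'
#' 3rd-order Butterworth band-pass at 10-13.5 Hz (`late_fast`) or 14.5-18 Hz
#' (`early_fast`), forward and backward. The 13.5-14.5 Hz gap between the two
#' bands is excluded from spindle identification by construction.
#'
#' @param x Signal in microvolts.
#' @param sampling_rate_hz Sampling rate; upper band edge must be below
#'   Nyquist.
#' @param band `"late_fast"`, `"early_fast"`, or a numeric `c(lo, hi)`.
#' @param order Prototype order.
#' @return Filtered signal, same length.
#' @export
bandpass_spindle <- function(x, sampling_rate_hz, band = "late_fast", order = 3L) {
  if (is.character(band)) {
    cfg <- swa_default_config()$filters
    if (!band %in% c("late_fast", "early_fast"))
      stop("band must be 'late_fast', 'early_fast', or numeric c(lo, hi)")
    edges <- cfg[[band]]$band
    order <- cfg[[band]]$order
  } else edges <- band
  if (edges[2L] >= sampling_rate_hz / 2)
    stop("upper band edge at or above Nyquist")
  sos <- cached_sos(order, edges, sampling_rate_hz, "pass")
  sos_filtfilt(sos, x)
}

#' Instantaneous amplitude (upper envelope) of a band-limited signal
#'
#' Magnitude of the analytic signal, computed by zeroing the negative
#' frequencies of the discrete Fourier transform.
#'
#' @param x Band-limited numeric signal.
#' @return Non-negative envelope, same length as `x`.
#' @export
upper_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Centered moving root-mean-square
#'
#' @param x Numeric signal.
#' @param window_n Window length in samples (>= 1); shrinks at the edges.
#' @return Moving RMS series, same length as `x`.
#' @export
moving_rms <- function(x, window_n) {
  n <- length(x)
  window_n <- max(1L, as.integer(window_n))
  half <- window_n %/% 2L
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}
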