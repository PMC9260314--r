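# Minimal EDF (European Data Format) support: 16-bit integer signals with the
# standard 256-byte header plus 256 bytes per signal. No installed R package
# in this stack reads EDF, so the format is implemented here directly; scope
# is plain EDF (no EDF+ annotations, no BDF).

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a minimal EDF file
#'
#' Signals are stored as 16-bit integers with per-signal physical scaling, in
#' 1 s data records. Used by the synthetic-data generator so the analysis
#' pipeline is exercised through its real file I/O path.
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (microvolts), equal lengths.
#' @param sampling_rate_hz Sampling rate; must be a positive integer (samples
#'   per 1 s data record).
#' @param subject_id Patient identification string.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, signals, sampling_rate_hz, subject_id = "X") {
  if (!is.list(signals) || is.null(names(signals)) || any(names(signals) == ""))
    stop("signals must be a named list of numeric vectors")
  fs <- sampling_rate_hz
  if (fs != round(fs) || fs <= 0)
    stop("sampling_rate_hz must be a positive integer for EDF writing")
  n <- unique(vapply(signals, length, 1L))
  if (length(n) != 1L) stop("all signals must have the same length")
  n_rec <- floor(n / fs)
  if (n_rec < 1L) stop("signal shorter than one data record")
  ns <- length(signals)

  phys_min <- phys_max <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]][seq_len(n_rec * fs)]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    phys_min[i] <- lo; phys_max[i] <- hi
    d <- round((x - lo) / (hi - lo) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(subject_id, 80),
    edf_pad("swacomp synthetic recording", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste(edf_pad(names(signals), 16), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep("uV", ns), 8), collapse = ""),
    paste(edf_pad(formatC(phys_min, format = "g", digits = 7), 8), collapse = ""),
    paste(edf_pad(formatC(phys_max, format = "g", digits = 7), 8), collapse = ""),
    paste(edf_pad(rep("-32768", ns), 8), collapse = ""),
    paste(edf_pad(rep("32767", ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep(fs, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # interleave: per record, all samples of signal 1, then signal 2, ...
  rec_mat <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (i in seq_len(ns)) {
    rec_mat[(i - 1L) * fs + seq_len(fs), ] <- matrix(dig[[i]], nrow = fs)
  }
  writeBin(as.integer(rec_mat), con, size = 2L, endian = "little")
  invisible(path)
}

# Parse an EDF header and return signal metadata.
read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  h <- list()
  h$version <- rd(8); h$patient <- rd(80); h$recording <- rd(80)
  h$startdate <- rd(8); h$starttime <- rd(8)
  h$header_bytes <- as.integer(rd(8)); rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_duration_s <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  ns <- h$ns
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  h$labels <- fld(16); h$transducer <- fld(80); h$phys_dim <- fld(8)
  h$phys_min <- as.numeric(fld(8)); h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8)); h$dig_max <- as.numeric(fld(8))
  h$prefilter <- fld(80)
  h$samples_per_record <- as.integer(fld(8)); fld(32)
  h
}

# Read all signals of an EDF file into a named list of numeric vectors
# (physical units), plus the per-signal sampling rates.
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  spr <- h$samples_per_record
  total_per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = total_per_rec * h$n_records,
                 size = 2L, endian = "little", signed = TRUE)
  if (length(raw) < total_per_rec * h$n_records)
    stop("EDF file truncated: ", path)
  offs <- c(0L, cumsum(spr))
  signals <- vector("list", h$ns)
  for (i in seq_len(h$ns)) {
    idx <- outer(offs[i] + seq_len(spr[i]),
                 (seq_len(h$n_records) - 1L) * total_per_rec, "+")
    d <- raw[as.vector(idx)]
    scale <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    signals[[i]] <- h$phys_min[i] + (d - h$dig_min[i]) * scale
  }
  names(signals) <- h$labels
  list(header = h,
       signals = signals,
       sampling_rates_hz = spr / h$record_duration_s)
}

# Locate a channel in an EDF label vector: exact label, "EEG <label>" prefix,
# or "<label>-<ref>" referenced form, case-insensitively.
match_edf_channel <- function(labels, channel_label, reference_label = NA) {
  norm <- toupper(gsub("^EEG[ _]*", "", trimws(labels)))
  want <- toupper(trimws(channel_label))
  hit <- which(norm == want)
  if (!length(hit) && !is.na(reference_label)) {
    hit <- which(norm == paste0(want, "-", toupper(trimws(reference_label))))
  }
  if (!length(hit)) hit <- which(sub("-.*$", "", norm) == want)
  if (!length(hit)) return(NA_integer_)
  hit[1L]
}

#' Read one referenced EEG channel from an EDF file
#'
#' Samples are converted from the EDF physical scaling to microvolts at read
#' time. When `reference_label` names a separately stored reference trace the
#' output is `channel - reference`; when the channel is stored pre-referenced
#' (e.g. labelled `"C3-A2"`) or `reference_label` is `NA`, the stored trace is
#' returned as-is.
#'
#' @param path Path to an EDF file.
#' @param channel_label Channel to read (e.g. `"FP1"`).
#' @param reference_label Reference electrode, or `NA` for none.
#' @param subject_id Subject identifier stamped on the result; defaults to the
#'   EDF patient field.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, channel_label, reference_label = NA,
                           subject_id = NULL) {
  edf <- read_edf(path)
  h <- edf$header
  i <- match_edf_channel(h$labels, channel_label, reference_label)
  if (is.na(i))
    stop("channel not found in EDF: ", channel_label,
         " (available: ", paste(h$labels, collapse = ", "), ")")
  x <- edf$signals[[i]]
  fs <- edf$sampling_rates_hz[i]
  ref_used <- NA_character_
  pre_referenced <- grepl("-", h$labels[i], fixed = TRUE)
  if (!is.na(reference_label) && !is.null(reference_label) && !pre_referenced) {
    j <- match_edf_channel(h$labels, reference_label)
    if (!is.na(j)) {
      if (edf$sampling_rates_hz[j] != fs)
        stop("channel and reference have different sampling rates")
      x <- x - edf$signals[[j]]
      ref_used <- as.character(reference_label)
    }
  } else if (!is.na(reference_label) && pre_referenced) {
    ref_used <- as.character(reference_label)
  }
  # microvolt conversion: EDF physical dimension may be mV or V
  dim_i <- tolower(h$phys_dim[i])
  if (dim_i %in% c("mv")) x <- x * 1000
  if (dim_i %in% c("v")) x <- x * 1e6
  eeg_recording(x, fs,
                subject_id = if (is.null(subject_id)) h$patient else subject_id,
                channel_label = channel_label,
                reference_label = ref_used)
}
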