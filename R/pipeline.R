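# Per-subject and multi-subject orchestration: detection -> coupling ->
# composition (-> optional time-frequency ROI power), with persisted event
# tables and a JSON report whose every number is recomputable from those
# tables.

#' Run the full pipeline for one subject
#'
#' For each `(sw_channel, spindle_channel)` pair: detect slow waves on the
#' slow-wave channel, detect late-fast and early-fast spindles on the spindle
#' channel, classify trough-locked coupling, and summarize composition as
#' wall-clock 2-min bins, stage-specific percentages, and 100 normalized-NREM
#' bins with the high-late-fast bin count. With `tfr = TRUE` the
#' baseline-normalized ROI power of both subtypes is computed as well (events
#' subsampled to `config$tfr$max_events`).
#'
#' @param edf_path Path to the subject's EDF file.
#' @param hypnogram_path Path to the hypnogram file.
#' @param channel_pairs List of `c(sw_channel, spindle_channel)` pairs.
#' @param config Configuration (see [swa_default_config()]).
#' @param hypnogram_dialect Dialect for [read_hypnogram()].
#' @param epoch_seconds Hypnogram epoch length.
#' @param reference_label Reference electrode passed to [read_recording()].
#' @param subject_id Subject identifier; defaults to the EDF patient field.
#' @param out_dir Optional directory; when given, event tables (TSV) and the
#'   report (JSON) are written there.
#' @param tfr Whether to compute ROI power (slower).
#' @return A `subject_report` list: per-channel event totals, per-pair
#'   coupling counts, stage compositions, normalized-NREM bin series, high-LF
#'   bin counts, optional ROI power, the configuration hash and package
#'   version.
#' @export
run_subject <- function(edf_path, hypnogram_path,
                        channel_pairs = list(c("CZ", "CZ")),
                        config = swa_default_config(),
                        hypnogram_dialect = "plain_text",
                        epoch_seconds = 30,
                        reference_label = NA,
                        subject_id = NULL,
                        out_dir = NULL, tfr = FALSE) {
  if (!file.exists(edf_path)) stop("missing EDF for subject: ", edf_path)
  if (!file.exists(hypnogram_path))
    stop("missing hypnogram for subject: ", edf_path)
  hyp <- read_hypnogram(hypnogram_path, hypnogram_dialect, epoch_seconds,
                        stage_map = config$stages[[hypnogram_dialect]])

  channels <- unique(unlist(channel_pairs))
  recs <- lapply(channels, function(ch)
    read_recording(edf_path, ch, reference_label, subject_id = subject_id))
  names(recs) <- channels
  sid <- if (is.null(subject_id)) recs[[1L]]$subject_id else subject_id
  for (rec in recs) check_paired(rec, hyp)
  dur <- recording_duration_s(recs[[1L]])

  sw_by_ch <- lapply(recs, detect_slow_waves, hyp = hyp, config = config)
  lf_by_ch <- lapply(recs, detect_spindles, hyp = hyp, band = "late_fast",
                     config = config)
  ef_by_ch <- lapply(recs, detect_spindles, hyp = hyp, band = "early_fast",
                     config = config)

  channel_totals <- lapply(channels, function(ch) {
    list(channel = ch,
         n_slow_waves = NROW(sw_by_ch[[ch]]),
         n_late_fast_spindles = NROW(lf_by_ch[[ch]]),
         n_early_fast_spindles = NROW(ef_by_ch[[ch]]))
  })
  names(channel_totals) <- channels

  pairs_out <- list()
  for (pair in channel_pairs) {
    swc <- pair[1L]; spc <- pair[2L]
    key <- paste0(swc, "-", spc)
    cl <- classify_coupling(sw_by_ch[[swc]], lf_by_ch[[spc]], ef_by_ch[[spc]],
                            window_s = config$coupling$window_s,
                            reference = config$coupling$reference,
                            sw_channel = swc, spindle_channel = spc)
    bins_wall <- bin_composition(cl$coupled, dur,
                                 config$composition$bin_width_s)
    bins_norm <- normalized_nrem_bins(cl$coupled, hyp,
                                      config$composition$n_norm_bins)
    stage_pct <- stage_percentages(cl$coupled, hyp)
    res <- list(
      channel_pair = key,
      n_coupled_lf = sum(cl$coupled$subtype == "LF_SW"),
      n_coupled_ef = sum(cl$coupled$subtype == "EF_SW"),
      n_unclassified = NROW(cl$unclassified),
      stage_composition = stage_pct,
      high_lf_bins = high_lf_bin_count(bins_norm,
                                       config$composition$high_lf_threshold_pct),
      coupled = cl$coupled,
      bins_wallclock = bins_wall,
      bins_normalized = bins_norm
    )
    if (tfr) {
      res$roi_power <- tryCatch(
        pair_roi_power(recs[[swc]], cl$coupled, sw_by_ch[[swc]], config),
        error = function(e) NULL)
    }
    pairs_out[[key]] <- res
  }

  report <- list(
    subject_id = sid,
    channels = channel_totals,
    pairs = pairs_out,
    config_hash = config_hash(config),
    software_version = as.character(utils::packageVersion("swacomp"))
  )
  class(report) <- "subject_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ch in channels) {
      write_event_table(sw_by_ch[[ch]],
                        file.path(out_dir, paste0(sid, "_", ch, "_sw.tsv")))
      write_event_table(lf_by_ch[[ch]],
                        file.path(out_dir, paste0(sid, "_", ch, "_lf.tsv")))
      write_event_table(ef_by_ch[[ch]],
                        file.path(out_dir, paste0(sid, "_", ch, "_ef.tsv")))
    }
    for (key in names(pairs_out)) {
      write_event_table(pairs_out[[key]]$coupled,
                        file.path(out_dir, paste0(sid, "_", key, "_coupled.tsv")))
      write_event_table(pairs_out[[key]]$bins_normalized,
                        file.path(out_dir, paste0(sid, "_", key, "_bins_norm.tsv")))
    }
    writeLines(report_json(report),
               file.path(out_dir, paste0(sid, "_report.json")))
  }
  report
}

# Serializable view of a subject report (event tables stripped to counts).
report_json <- function(report) {
  slim <- report
  for (key in names(slim$pairs)) {
    slim$pairs[[key]]$coupled <- NULL
    slim$pairs[[key]]$bins_wallclock <- NULL
    slim$pairs[[key]]$bins_normalized <- NULL
  }
  as.character(jsonlite::toJSON(unclass(slim), auto_unbox = TRUE, digits = 10,
                                dataframe = "columns", pretty = TRUE))
}

# ROI power of LF_SW vs EF_SW coupled events on one channel.
pair_roi_power <- function(recording, coupled, all_sw, config) {
  fs <- recording$sampling_rate_hz
  x <- recording$samples
  tf <- config$tfr
  freqs <- seq(tf$freq_lo_hz, tf$freq_hi_hz, by = tf$freq_step_hz)
  out <- list()
  for (sub in c("LF_SW", "EF_SW")) {
    ev <- coupled[coupled$subtype == sub, , drop = FALSE]
    if (!NROW(ev)) { out[[sub]] <- NA_real_; next }
    if (NROW(ev) > tf$max_events)
      ev <- ev[seq(1L, NROW(ev), length.out = tf$max_events), , drop = FALSE]
    ev <- data.frame(t_trough_s = ev$sw_t_trough_s)
    peri <- peri_event_segments(x, ev, fs, tf$half_width_s)
    base <- baseline_segments(x, ev[peri$kept, , drop = FALSE], all_sw, fs,
                              tf$half_width_s)
    if (!NROW(peri$segments) || !NROW(base$segments)) {
      out[[sub]] <- NA_real_; next
    }
    times <- seq_len(ncol(peri$segments)) / fs - tf$half_width_s
    ev_maps <- lapply(seq_len(nrow(peri$segments)), function(i)
      morlet_tfr(peri$segments[i, ], fs, tf$n_cycles, freqs, times))
    ba_maps <- lapply(seq_len(nrow(base$segments)), function(i)
      morlet_tfr(base$segments[i, ], fs, tf$n_cycles, freqs, times))
    norm <- normalize_and_average(ev_maps, ba_maps)
    roi <- config$rois[[if (sub == "LF_SW") "late_fast" else "early_fast"]]
    out[[sub]] <- roi_power(norm, roi)
  }
  out
}

#' Run a multi-subject study
#'
#' Executes [run_subject()] for every row of the manifest, collects
#' per-subject failures without aborting the study, builds group tables of
#' event totals and stage compositions, and runs the group-level statistics:
#' an event-count-weighted t-test of N3 vs N2 late-fast percentage per
#' channel pair and, when the manifest defines two groups, the between-group
#' weighted t-test of overall late-fast percentage and the clustered
#' negative-binomial comparison of high-late-fast bin counts.
#'
#' @param manifest data.frame with columns `subject_id`, `edf`, `hypnogram`,
#'   optional `group`, optional `channel_pairs` (semicolon-separated
#'   `SW:SP` pairs, e.g. `"FP1:CZ;CZ:CZ"`).
#' @param config Configuration list.
#' @param hypnogram_dialect,epoch_seconds Passed to [run_subject()].
#' @param out_dir Optional output directory for per-subject artifacts.
#' @param tfr Whether to compute ROI power per subject.
#' @return A `study_report` list: `subjects` (reports), `failures`,
#'   `subject_table` (data.frame), `stats`.
#' @export
run_study <- function(manifest, config = swa_default_config(),
                      hypnogram_dialect = "plain_text", epoch_seconds = 30,
                      out_dir = NULL, tfr = FALSE) {
  if (!NROW(manifest)) stop("empty study manifest")
  need <- c("subject_id", "edf", "hypnogram")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  reports <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    pairs <- if ("channel_pairs" %in% names(manifest) &&
                 nzchar(row$channel_pairs)) {
      lapply(strsplit(strsplit(row$channel_pairs, ";")[[1L]], ":"),
             function(p) c(p[1L], p[length(p)]))
    } else list(c("CZ", "CZ"))
    res <- tryCatch(
      run_subject(row$edf, row$hypnogram, pairs, config,
                  hypnogram_dialect, epoch_seconds,
                  subject_id = row$subject_id,
                  out_dir = if (is.null(out_dir)) NULL
                  else file.path(out_dir, row$subject_id),
                  tfr = tfr),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[row$subject_id]] <- conditionMessage(res)
    } else {
      reports[[row$subject_id]] <- res
    }
  }
  if (!length(reports)) stop("all subjects failed: ",
                             paste(unlist(failures), collapse = "; "))

  tab <- do.call(rbind, lapply(names(reports), function(sid) {
    rep <- reports[[sid]]
    grp <- if ("group" %in% names(manifest))
      manifest$group[manifest$subject_id == sid][1L] else "all"
    do.call(rbind, lapply(rep$pairs, function(p) {
      sc <- p$stage_composition
      data.frame(subject_id = sid, group = grp, channel_pair = p$channel_pair,
                 n_coupled_lf = p$n_coupled_lf, n_coupled_ef = p$n_coupled_ef,
                 n_unclassified = p$n_unclassified,
                 pct_lf_overall = 100 * p$n_coupled_lf /
                   max(p$n_coupled_lf + p$n_coupled_ef, 1L),
                 pct_lf_n2 = sc$pct_lf[sc$stage == "N2"],
                 pct_lf_n3 = sc$pct_lf[sc$stage == "N3"],
                 n_coupled_n2 = sc$n_lf[sc$stage == "N2"] + sc$n_ef[sc$stage == "N2"],
                 n_coupled_n3 = sc$n_lf[sc$stage == "N3"] + sc$n_ef[sc$stage == "N3"],
                 high_lf_bins = p$high_lf_bins)
    }))
  }))
  rownames(tab) <- NULL

  stats_out <- list()
  for (key in unique(tab$channel_pair)) {
    sub <- tab[tab$channel_pair == key &
                 !is.na(tab$pct_lf_n3) & !is.na(tab$pct_lf_n2), ]
    if (nrow(sub) >= 2L) {
      stats_out[[paste0("n3_vs_n2_pct_lf_", key)]] <- weighted_ttest(
        sub$pct_lf_n3, pmax(sub$n_coupled_n3, 1L),
        sub$pct_lf_n2, pmax(sub$n_coupled_n2, 1L))
    }
  }
  groups <- unique(tab$group)
  if (length(groups) == 2L) {
    a <- tab[tab$group == groups[1L], ]
    b <- tab[tab$group == groups[2L], ]
    if (nrow(a) >= 2L && nrow(b) >= 2L) {
      stats_out$group_pct_lf <- weighted_ttest(
        a$pct_lf_overall, pmax(a$n_coupled_lf + a$n_coupled_ef, 1L),
        b$pct_lf_overall, pmax(b$n_coupled_lf + b$n_coupled_ef, 1L))
      # keep manifest group order so the ratio reads group2 / group1
      stats_out$group_high_lf_bins <- clustered_nb_count_ratio(
        c(a$high_lf_bins, b$high_lf_bins),
        factor(c(rep(groups[1L], nrow(a)), rep(groups[2L], nrow(b))),
               levels = groups),
        c(a$subject_id, b$subject_id))
    }
  }

  out <- list(subjects = reports, failures = failures,
              subject_table = tab, stats = stats_out,
              config_hash = config_hash(config))
  class(out) <- "study_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_table(tab, file.path(out_dir, "subject_table.tsv"))
  }
  out
}
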