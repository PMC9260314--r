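#' Read a hypnogram file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`plain_text`}{Whitespace/newline-separated stage tokens
#'     (`W N1 N2 N3 REM`), one token per epoch.}
#'   \item{`dreams`}{Numeric per-line scores as distributed with the DREAMS
#'     database (one value per 5 s by default there; pass the matching
#'     `epoch_seconds`). A non-numeric first line is skipped.}
#'   \item{`nsrr_xml`}{NSRR annotation XML; `<SleepStage>` elements carry
#'     numeric stage codes.}
#' }
#' Unknown tokens map to `UNSCORABLE`. Token-to-stage tables live in the
#' configuration (`stages` section of [swa_default_config()]) so site-specific
#' codes can be supplied without code changes.
#'
#' @param path Path to the hypnogram file.
#' @param dialect One of `"plain_text"`, `"dreams"`, `"nsrr_xml"`.
#' @param epoch_seconds Epoch length of the file's scores.
#' @param stage_map Optional named character vector overriding the dialect's
#'   token-to-stage table.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("plain_text", "dreams", "nsrr_xml"),
                           epoch_seconds = 30, stage_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  if (is.null(stage_map)) stage_map <- swa_default_config()$stages[[dialect]]

  tokens <- switch(dialect,
    plain_text = {
      toks <- scan(path, what = "", quiet = TRUE)
      if (!length(toks)) stop("empty hypnogram file: ", path)
      toupper(toks)
    },
    dreams = {
      lines <- readLines(path, warn = FALSE)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines)]
      if (!length(lines)) stop("empty hypnogram file: ", path)
      # DREAMS files open with a header line naming the signal
      if (is.na(suppressWarnings(as.numeric(lines[1L])))) lines <- lines[-1L]
      if (!length(lines)) stop("hypnogram file has no scores: ", path)
      lines
    },
    nsrr_xml = {
      doc <- xml2::read_xml(path)
      nodes <- xml2::xml_find_all(doc, ".//SleepStage")
      if (!length(nodes)) stop("no SleepStage elements found in: ", path)
      xml2::xml_text(nodes)
    })

  stages <- unname(stage_map[tokens])
  stages[is.na(stages)] <- "UNSCORABLE"
  hypnogram(stages, epoch_seconds)
}

#' Write a hypnogram as plain text
#'
#' One stage token per line; round-trips through
#' `read_hypnogram(dialect = "plain_text")`.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(hyp$stages, path)
  invisible(path)
}
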