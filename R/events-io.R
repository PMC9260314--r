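#' Write an event table
#'
#' Events (slow waves, spindles, or coupled events) are persisted as
#' tab-separated values with a header; numeric columns are written at full
#' double precision so a write-then-read round trip reproduces the table
#' exactly. An empty event set yields a header-only file.
#'
#' @param events A data.frame of events (homogeneous rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_event_table <- function(events, path) {
  if (!is.data.frame(events)) stop("events must be a data.frame")
  out <- events
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- formatC(out[[j]], format = "g", digits = 17)
      out[[j]][out[[j]] == "NA"] <- NA
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write event table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path Path to a tab-separated event table.
#' @return A data.frame of events.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
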