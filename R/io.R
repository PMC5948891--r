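#' Write / read a session recording as a delimited container
#'
#' The package's on-disk interchange format for recordings: a gzip-compressed
#' tab-separated sample matrix (`<basename>.tsv.gz`, one column per channel,
#' one row per sample, header = channel labels) plus a JSON sidecar
#' (`<basename>.json`) holding the sampling rate, channel labels, cue
#' annotations and day index. Self-contained and readable by the
#' preprocessing module.
#'
#' @param rec A `session_recording`.
#' @param basename Path prefix; the two files are written next to it.
#' @return `write_session()`: the basename, invisibly; `read_session()`: a
#'   `session_recording`.
#' @export
write_session <- function(rec, basename) {
  stopifnot(inherits(rec, "session_recording"))
  con <- gzfile(paste0(basename, ".tsv.gz"), "w")
  on.exit(close(con), add = TRUE)
  utils::write.table(t(rec$samples), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = rec$channel_labels)
  side <- list(sampling_rate_hz = rec$sampling_rate_hz,
               channel_labels = rec$channel_labels,
               day = rec$day,
               events = rec$events[, intersect(c("label", "onset_s",
                                                 "duration_s", "trial"),
                                               names(rec$events))])
  jsonlite::write_json(side, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' @rdname write_session
#' @export
read_session <- function(basename) {
  side <- jsonlite::fromJSON(paste0(basename, ".json"))
  tab <- utils::read.table(gzfile(paste0(basename, ".tsv.gz")), header = TRUE,
                           sep = "\t", check.names = FALSE)
  samples <- t(as.matrix(tab))
  rownames(samples) <- side$channel_labels
  events <- as.data.frame(side$events)
  class(events) <- c("mi_schedule", "data.frame")
  structure(list(samples = samples,
                 sampling_rate_hz = side$sampling_rate_hz,
                 channel_labels = side$channel_labels,
                 events = events,
                 day = side$day %||% 1L),
            class = "session_recording")
}
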