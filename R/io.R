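#' Read / write package tables and objects as plain text
#'
#' Recordings are written as TSV (rows = samples, columns = channels,
#' plus a `state` column when labeled) with a YAML sidecar
#' (`<path>.yaml`) holding the sampling rate and channel names.
#' Connectomes are square TSV without header; segment and timescale
#' tables are plain TSV.
#'
#' @param recording a [Recording-class].
#' @param path file path (TSV).
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns a [Recording-class].
#' @name recording-io
NULL

#' @rdname recording-io
#' @export
writeRecording <- function(recording, path) {
  df <- as.data.frame(signals(recording))
  if (length(stateLabels(recording))) df$state <- stateLabels(recording)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = samplingRate(recording),
                        channels = colnames(signals(recording))),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname recording-io
#' @export
readRecording <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  labels <- if ("state" %in% names(df)) as.character(df$state) else character()
  sig <- as.matrix(df[, unlist(meta$channels), drop = FALSE])
  Recording(sig, fs = meta$fs, labels = labels)
}

#' @rdname recording-io
#' @param connectome a [Connectome-class].
#' @export
writeConnectome <- function(connectome, path) {
  utils::write.table(couplingMatrix(connectome), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname recording-io
#' @export
readConnectome <- function(path) {
  Connectome(as.matrix(utils::read.table(path, header = FALSE, sep = "\t")))
}

#' @rdname recording-io
#' @param table a segment or timescale data.frame.
#' @export
writeTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname recording-io
#' @export
readTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
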