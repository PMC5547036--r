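#' Plain-text sidecar tables: events, montages, feature tables
#'
#' Event tables are TSV with columns \code{onset_sample} (0-based),
#' \code{onset_sec}, \code{code}, \code{label}. Montages are TSV with
#' columns \code{label}, \code{x}, \code{y}, \code{z} on a unit-radius head
#' frame. Feature tables are TSV with columns \code{subject_id},
#' \code{record_id}, \code{label}, then \code{f1..fk}.
#'
#' @param events event matrix data.frame.
#' @param rate sampling rate in Hz, used to derive \code{onset_sec}.
#' @param path file path.
#' @return readers return data.frames; writers return the path invisibly.
#' @name sidecar-io
NULL

#' @rdname sidecar-io
#' @export
writeEventsTsv <- function(events, rate, path) {
  out <- data.frame(onset_sample = events$onset_sample,
                    onset_sec = events$onset_sample / rate,
                    code = events$code, label = events$label)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sidecar-io
#' @export
readEventsTsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(onset_sample = as.integer(ev$onset_sample),
             code = as.integer(ev$code),
             label = as.character(ev$label), stringsAsFactors = FALSE)
}

#' @rdname sidecar-io
#' @param montage data.frame(label, x, y, z).
#' @export
writeMontageTsv <- function(montage, path) {
  utils::write.table(montage[, c("label", "x", "y", "z")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sidecar-io
#' @export
readMontageTsv <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  m$label <- as.character(m$label)
  m[, c("label", "x", "y", "z")]
}

#' @rdname sidecar-io
#' @param table feature table data.frame(subject_id, record_id, label, f1..).
#' @export
writeFeatureTsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sidecar-io
#' @export
readFeatureTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$subject_id <- as.character(tab$subject_id)
  tab$record_id <- as.character(tab$record_id)
  tab
}
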