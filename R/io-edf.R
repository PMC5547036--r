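#' Read and write European Data Format (EDF/EDF+) files
#'
#' Minimal EDF/EDF+ support sufficient for multi-site ERP work: continuous
#' multichannel signals with per-channel physical scaling, and (for EDF+)
#' an embedded annotations signal carrying the event markers as
#' time-stamped annotation lists. Signals are quantized to 16-bit integers
#' per the EDF standard, so a write/read round trip preserves data to
#' within one quantization step of the per-channel physical range.
#'
#' Events are embedded as annotations with text \code{"<code>/<label>"} and
#' are additionally written as a sidecar TSV by [writeEventsTsv()]; the
#' reader reconstructs the event matrix from the annotations. The
#' recording-id header field carries the dataset id and reference
#' descriptor (\code{"ref:<scheme>"}).
#'
#' @param rec an [EEGRecording-class].
#' @param path file path.
#' @param embedEvents embed events as an EDF+ annotations signal.
#' @return \code{writeEdf}: the path, invisibly. \code{readEdf}: an
#'   [EEGRecording-class] (channel positions are not stored in EDF; attach
#'   them from a montage TSV).
#' @seealso [readMontageTsv()], [writeEventsTsv()]
#' @export
writeEdf <- function(rec, path, embedEvents = TRUE) {
  stopifnot(is(rec, "EEGRecording"))
  data <- rec@data
  nch <- nrow(data)
  ns <- ncol(data)
  rate <- rec@samplingRate
  # one EDF data record per second when the sample count divides evenly,
  # otherwise a single record spanning the file
  if (abs(rate - round(rate)) < 1e-9 && ns %% round(rate) == 0) {
    spr <- as.integer(round(rate)); recDur <- 1; nrec <- ns %/% spr
  } else {
    spr <- ns; recDur <- ns / rate; nrec <- 1L
  }

  # physical/digital scaling per channel
  physMax <- apply(abs(data), 1, max)
  physMax <- ifelse(physMax > 0, ceiling(physMax * 1.01), 1)
  digMax <- 32767; digMin <- -32768
  dig <- round(sweep(data, 1, physMax / digMax, "/"))
  dig[dig > digMax] <- digMax; dig[dig < digMin] <- digMin

  annot <- embedEvents && nrow(rec@events) > 0
  # annotation byte stream: one NUL-terminated timekeeping TAL per record;
  # all event TALs (each NUL-terminated) ride in record 1
  annBytes <- NULL
  if (annot) {
    tal <- function(s) c(charToRaw(s), as.raw(0))
    evTals <- unlist(lapply(seq_len(nrow(rec@events)), function(i) {
      ev <- rec@events[i, ]
      tal(sprintf("+%.7g\x14%d/%s\x14", ev$onset_sample / rate, ev$code,
                  ev$label))
    }))
    rawPerRec <- lapply(seq_len(nrec) - 1, function(r) {
      b <- tal(sprintf("+%.7g\x14\x14", r * recDur))
      if (r == 0) c(b, evTals) else b
    })
    annSpr <- as.integer(ceiling(max(lengths(rawPerRec)) / 2))
    annBytes <- lapply(rawPerRec, function(b) c(b, raw(annSpr * 2 - length(b))))
  }

  nsig <- nch + as.integer(annot)
  headerBytes <- 256L + 256L * nsig
  pad <- function(x, w) {
    x <- as.character(x)
    x <- substr(x, 1, w)
    sprintf(sprintf("%%-%ds", w), x)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("Startdate 01-JAN-2000 %s ref:%s", rec@id, rec@reference), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(headerBytes, 8)
  wr(if (annot) "EDF+C" else "", 44)
  wr(nrec, 8)
  wr(format(recDur, digits = 7), 8)
  wr(nsig, 4)
  labs <- c(rec@channelLabels, if (annot) "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(nsig)) wr("", 80)                       # transducer
  for (i in seq_len(nsig)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(nsig)) wr(if (i <= nch) -physMax[i] else -1, 8)
  for (i in seq_len(nsig)) wr(if (i <= nch) physMax[i] else 1, 8)
  for (i in seq_len(nsig)) wr(digMin, 8)
  for (i in seq_len(nsig)) wr(digMax, 8)
  for (i in seq_len(nsig)) wr("", 80)                       # prefilter
  for (i in seq_len(nsig)) wr(if (i <= nch) spr else length(annBytes[[1]]) / 2, 8)
  for (i in seq_len(nsig)) wr("", 32)

  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(nch))
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
    if (annot) writeBin(annBytes[[r]], con)
  }
  invisible(path)
}

#' @rdname writeEdf
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("not an EDF file: ", path)
  rd(80)                                   # patient
  recfield <- rd(80)
  rd(8); rd(8)
  headerBytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  labs <- vapply(seq_len(nsig), function(i) rd(16), "")
  for (i in seq_len(nsig)) rd(80)
  dims <- vapply(seq_len(nsig), function(i) rd(8), "")
  physMin <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  for (i in seq_len(nsig)) rd(80)
  spr <- as.integer(vapply(seq_len(nsig), function(i) rd(8), ""))
  for (i in seq_len(nsig)) rd(32)
  seek(con, headerBytes)

  isAnn <- labs == "EDF Annotations"
  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) sig[[i]] <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nsig)) {
      if (isAnn[i]) {
        sig[[i]][[r]] <- readBin(con, "raw", n = spr[i] * 2)
      } else {
        sig[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2,
                                 signed = TRUE, endian = "little")
      }
    }
  }
  chIdx <- which(!isAnn)
  nch <- length(chIdx)
  nsamp <- spr[chIdx[1]] * nrec
  data <- matrix(0, nch, nsamp)
  for (k in seq_along(chIdx)) {
    i <- chIdx[k]
    raw <- unlist(sig[[i]])
    scale <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    data[k, ] <- (raw - digMin[i]) * scale + physMin[i]
  }
  rate <- spr[chIdx[1]] / recDur

  events <- emptyEvents()
  if (any(isAnn)) {
    talRaw <- unlist(sig[[which(isAnn)[1]]])
    # TALs are NUL-separated; fields within a TAL are 0x14-separated
    nulAt <- which(talRaw == as.raw(0))
    starts <- c(1L, utils::head(nulAt, -1) + 1L)
    parts <- vapply(seq_along(nulAt), function(i) {
      seg <- talRaw[starts[i]:(nulAt[i] - 1L)]
      if (length(seg)) rawToChar(seg[seg != as.raw(0)]) else ""
    }, "")
    for (p in parts) {
      fields <- strsplit(p, "\x14", fixed = TRUE)[[1]]
      if (length(fields) >= 2 && nzchar(fields[2])) {
        onset <- as.numeric(sub("^\\+", "", strsplit(fields[1], "\x15")[[1]][1]))
        m <- regmatches(fields[2], regexec("^(-?[0-9]+)/(.*)$", fields[2]))[[1]]
        if (length(m) == 3) {
          events <- rbind(events, data.frame(
            onset_sample = as.integer(round(onset * rate)),
            code = as.integer(m[2]), label = m[3], stringsAsFactors = FALSE))
        }
      }
    }
    if (nrow(events)) events <- events[order(events$onset_sample), , drop = FALSE]
    rownames(events) <- NULL
  }

  id <- "recording"; ref <- "unknown"
  m <- regmatches(recfield, regexec("Startdate \\S+ (\\S+) ref:(\\S+)", recfield))[[1]]
  if (length(m) == 3) { id <- m[2]; ref <- m[3] }
  newRecording(id = id, data = data, samplingRate = rate,
               channelLabels = labs[chIdx], reference = ref,
               events = events, meta = list(source_file = path))
}
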