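#' Acquisition protocol for pre-sharing quality control
#'
#' Declarative statement of the study's acquisition standard, checked
#' file-by-file before upload by [runQc()].
#'
#' @param expectedRate Hz.
#' @param requiredChannels channel labels that must be present.
#' @param requiredEventCodes integer codes that must occur at least once.
#' @param impedanceThreshold kOhm; impedances recorded in the file's
#'   metadata must stay below it (default 5).
#' @param filenamePattern regular expression the file name must match;
#'   the default encodes \code{<study>_<site>_<subject>_<visit>_<task>}.
#' @param bandwidth expected acquisition band c(low, high) Hz (recorded;
#'   informational).
#' @param forbiddenHeaderPatterns regexes scanned against header fields
#'   for identifying information (names, dates of birth).
#' @param lineFreq mains frequency, 60 (default) or 50 Hz.
#' @param flatTolerance,noiseMultiplier,lineFraction bad-channel
#'   thresholds; see [detectBadChannels()].
#' @return list of class \code{"qcProtocol"}.
#' @export
qcProtocol <- function(expectedRate, requiredChannels,
                       requiredEventCodes = integer(),
                       impedanceThreshold = 5,
                       filenamePattern =
                         "^[A-Za-z0-9]+_[A-Za-z0-9]+_[A-Za-z0-9]+_[A-Za-z0-9]+_[A-Za-z0-9]+\\.(edf|EDF)$",
                       bandwidth = c(0.1, 100),
                       forbiddenHeaderPatterns =
                         c("[A-Z][a-z]+ [A-Z][a-z]+",
                           "[0-9]{2}[-/.][0-9]{2}[-/.][0-9]{2,4}"),
                       lineFreq = 60, flatTolerance = 0.5,
                       noiseMultiplier = 5, lineFraction = 0.5) {
  if (impedanceThreshold <= 0)
    stop("configuration error: impedanceThreshold must be > 0", call. = FALSE)
  if (!nzchar(filenamePattern))
    stop("configuration error: filenamePattern must be non-empty",
         call. = FALSE)
  structure(list(expectedRate = expectedRate,
                 requiredChannels = requiredChannels,
                 requiredEventCodes = as.integer(requiredEventCodes),
                 impedanceThreshold = impedanceThreshold,
                 filenamePattern = filenamePattern, bandwidth = bandwidth,
                 forbiddenHeaderPatterns = forbiddenHeaderPatterns,
                 lineFreq = lineFreq, flatTolerance = flatTolerance,
                 noiseMultiplier = noiseMultiplier,
                 lineFraction = lineFraction),
            class = "qcProtocol")
}

#' Detect flat, noisy and line-dominated channels
#'
#' Flags channels that are flat (range below \code{flatTolerance} over the
#' whole recording, e.g. disconnected), high-noise (robust variance above
#' \code{noiseMultiplier} times the median robust channel variance), or
#' line-noise dominated (power within +/-1 Hz of the line frequency
#' exceeding \code{lineFraction} of total power).
#'
#' @param rec an [EEGRecording-class].
#' @param flatTolerance microvolts.
#' @param noiseMultiplier multiple of the median robust variance.
#' @param lineFreq line frequency Hz.
#' @param lineFraction power fraction threshold.
#' @return data.frame(channel, reason); zero rows when clean.
#' @export
detectBadChannels <- function(rec, flatTolerance = 0.5, noiseMultiplier = 5,
                              lineFreq = 60, lineFraction = 0.5) {
  if (flatTolerance <= 0 || noiseMultiplier <= 0)
    stop("configuration error: thresholds must be > 0", call. = FALSE)
  d <- rec@data
  n <- ncol(d)
  rate <- rec@samplingRate
  rng <- apply(d, 1, function(x) diff(range(x)))
  rvar <- apply(d, 1, function(x) stats::mad(x)^2)
  medVar <- stats::median(rvar[rng >= flatTolerance])
  if (!is.finite(medVar)) medVar <- Inf

  freq <- (seq_len(n) - 1) / n * rate
  lineBand <- freq >= lineFreq - 1 & freq <= lineFreq + 1
  lineFrac <- if (lineFreq < rate / 2) apply(d, 1, function(x) {
    P <- Mod(stats::fft(x))^2
    P <- P[freq <= rate / 2]
    tot <- sum(P[-1])
    if (tot == 0) 0 else sum(P[lineBand[freq <= rate / 2]]) / tot
  }) else rep(0, nrow(d))

  out <- data.frame(channel = character(), reason = character(),
                    stringsAsFactors = FALSE)
  add <- function(ix, reason) {
    if (any(ix)) rbind(out, data.frame(channel = rec@channelLabels[ix],
                                       reason = reason,
                                       stringsAsFactors = FALSE)) else out
  }
  out <- add(rng < flatTolerance, "flat")
  out <- add(rng >= flatTolerance & lineFrac > lineFraction, "line-noise")
  out <- add(rng >= flatTolerance & rvar > noiseMultiplier * medVar &
               !(rec@channelLabels %in% out$channel), "noisy")
  out
}

#' Scan header fields for identifying information
#'
#' Matches every header field against each forbidden pattern and reports
#' the field name and matched span; an empty finding set means the file is
#' de-identified with respect to the patterns.
#'
#' @param headerFields named character list/vector of header fields.
#' @param patterns character vector of regular expressions.
#' @return data.frame(field, pattern, match); zero rows = pass.
#' @export
scanHeaderDeid <- function(headerFields, patterns) {
  for (p in patterns) {
    ok <- tryCatch({ grepl(p, ""); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("configuration error: invalid pattern: ", p, call. = FALSE)
  }
  out <- data.frame(field = character(), pattern = character(),
                    match = character(), stringsAsFactors = FALSE)
  for (f in names(headerFields)) {
    txt <- as.character(headerFields[[f]])
    for (p in patterns) {
      m <- regmatches(txt, gregexpr(p, txt))[[1]]
      if (length(m))
        out <- rbind(out, data.frame(field = f, pattern = p, match = m,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

qcCheck <- function(name, status, detail = "") {
  data.frame(name = name, status = status, detail = detail,
             stringsAsFactors = FALSE)
}

#' Run the pre-sharing quality-control battery
#'
#' Checks, in order: file readable/uncorrupted (with checksum invariance —
#' QC never modifies the input), sampling rate equals the protocol rate,
#' required channels present, required event codes present with nonzero
#' count, recorded impedances below threshold (pass-with-warning when no
#' impedance metadata exists), bad-channel scan, de-identification header
#' scan, and file-name convention. One report entry per check; overall
#' pass iff no check fails.
#'
#' @param rec an [EEGRecording-class], or a path to an EDF file.
#' @param filename name checked against the protocol's pattern (default:
#'   basename of the path when \code{rec} is a path).
#' @param protocol a [qcProtocol()].
#' @return a \code{"qcReport"}: list(checks = data.frame(name, status,
#'   detail), overall).
#' @export
runQc <- function(rec, filename = NULL, protocol) {
  stopifnot(inherits(protocol, "qcProtocol"))
  checks <- qcCheck(character(), character(), character())
  if (is.character(rec)) {
    path <- rec
    if (is.null(filename)) filename <- basename(path)
    sumBefore <- md5OfFile(path)
    rec <- tryCatch(readEdf(path), error = function(e) e)
    if (inherits(rec, "error")) {
      checks <- qcCheck("corrupt", "fail",
                        paste("unreadable file:", conditionMessage(rec)))
      return(structure(list(checks = checks, overall = "fail"),
                       class = "qcReport"))
    }
    sumAfter <- md5OfFile(path)
    checks <- rbind(checks, qcCheck(
      "readable", if (identical(sumBefore, sumAfter)) "pass" else "fail",
      sprintf("md5 %s", sumBefore)))
  } else {
    checks <- rbind(checks, qcCheck("readable", "pass", "in-memory object"))
  }
  if (is.null(filename)) filename <- paste0(rec@id, ".edf")

  rateOk <- abs(rec@samplingRate - protocol$expectedRate) < 1e-6
  checks <- rbind(checks, qcCheck(
    "sampling_rate", if (rateOk) "pass" else "fail",
    sprintf("expected %g Hz, found %g Hz", protocol$expectedRate,
            rec@samplingRate)))

  missingCh <- setdiff(protocol$requiredChannels, rec@channelLabels)
  checks <- rbind(checks, qcCheck(
    "required_channels", if (!length(missingCh)) "pass" else "fail",
    if (length(missingCh)) paste("missing:", paste(missingCh, collapse = ", "))
    else sprintf("all %d present", length(protocol$requiredChannels))))

  codes <- table(factor(rec@events$code, levels = protocol$requiredEventCodes))
  missingCodes <- protocol$requiredEventCodes[codes == 0]
  checks <- rbind(checks, qcCheck(
    "event_codes",
    if (!length(protocol$requiredEventCodes) || !length(missingCodes))
      "pass" else "fail",
    if (length(missingCodes))
      paste("absent code(s):", paste(missingCodes, collapse = ", "))
    else paste(sum(codes), "required-code events")))

  imp <- rec@meta$impedances
  if (is.null(imp)) {
    checks <- rbind(checks, qcCheck("impedance", "warn",
                                    "no impedance metadata recorded"))
  } else {
    over <- names(imp)[imp >= protocol$impedanceThreshold]
    checks <- rbind(checks, qcCheck(
      "impedance", if (!length(over)) "pass" else "fail",
      if (length(over)) sprintf("above %g kOhm: %s",
                                protocol$impedanceThreshold,
                                paste(over, collapse = ", "))
      else sprintf("all below %g kOhm", protocol$impedanceThreshold)))
  }

  bad <- detectBadChannels(rec, protocol$flatTolerance,
                           protocol$noiseMultiplier, protocol$lineFreq,
                           protocol$lineFraction)
  checks <- rbind(checks, qcCheck(
    "bad_channels", if (!nrow(bad)) "pass" else "fail",
    if (nrow(bad)) paste(sprintf("%s (%s)", bad$channel, bad$reason),
                         collapse = ", ") else "none flagged"))

  header <- c(list(id = rec@id),
              lapply(rec@meta[vapply(rec@meta, is.character, TRUE)],
                     identity))
  findings <- scanHeaderDeid(header, protocol$forbiddenHeaderPatterns)
  checks <- rbind(checks, qcCheck(
    "deidentification", if (!nrow(findings)) "pass" else "fail",
    if (nrow(findings)) paste(sprintf("%s: '%s'", findings$field,
                                      findings$match), collapse = "; ")
    else "no identifying patterns"))

  nameOk <- grepl(protocol$filenamePattern, filename)
  checks <- rbind(checks, qcCheck(
    "filename", if (nameOk) "pass" else "fail",
    sprintf("expected pattern %s, actual '%s'", protocol$filenamePattern,
            filename)))

  overall <- if (any(checks$status == "fail")) "fail" else "pass"
  structure(list(checks = checks, overall = overall), class = "qcReport")
}

#' @export
print.qcReport <- function(x, ...) {
  cat("QC report:", x$overall, "\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %-18s %s\n", x$checks$status[i], x$checks$name[i],
                x$checks$detail[i]))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a \code{"qcReport"}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeQcReport <- function(report, path) {
  jsonlite::write_json(list(overall = report$overall,
                            checks = report$checks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
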