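#' Segment a recording into epochs (Step 1)
#'
#' Extracts one trial per event whose code is in \code{codes} and whose
#' window \code{[start, end)} (seconds relative to onset, half-open) lies
#' fully inside the recording. Events too close to the edges are dropped
#' and reported in \code{meta$dropped_events}.
#'
#' @param rec an [EEGRecording-class].
#' @param window c(start, end) seconds, \code{start < end}.
#' @param codes event codes to epoch around (default: all codes present).
#' @return an [EEGEpochs-class].
#' @export
epochRecording <- function(rec, window = c(-0.2, 0.8), codes = NULL) {
  if (window[1] >= window[2])
    stop("configuration error: window start must precede end", call. = FALSE)
  ev <- rec@events
  if (is.null(codes)) codes <- unique(ev$code)
  if (!length(codes)) stop("empty-epochs error: no event codes requested",
                           call. = FALSE)
  ev <- ev[ev$code %in% codes, , drop = FALSE]
  if (!nrow(ev))
    stop("empty-epochs error: no events match the requested codes",
         call. = FALSE)
  rate <- rec@samplingRate
  s0 <- round(window[1] * rate)
  s1 <- round(window[2] * rate)          # half-open: samples s0 .. s1-1
  len <- s1 - s0
  first <- ev$onset_sample + s0          # 0-based
  last <- ev$onset_sample + s1 - 1
  ok <- first >= 0 & last <= ncol(rec@data) - 1
  dropped <- which(!ok)
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev))
    stop("empty-epochs error: all matching events fall outside the recording",
         call. = FALSE)
  n <- nrow(ev)
  nch <- nChannels(rec)
  data <- array(0, c(n, nch, len))
  for (i in seq_len(n)) {
    idx <- (ev$onset_sample[i] + s0 + 1):(ev$onset_sample[i] + s1)
    data[i, , ] <- rec@data[, idx]
  }
  new("EEGEpochs", data = data, timeAxis = (s0:(s1 - 1)) / rate,
      trialCodes = as.integer(ev$code), trialIndices = seq_len(n),
      channelLabels = rec@channelLabels,
      channelPositions = rec@channelPositions,
      samplingRate = rate, reference = rec@reference,
      cellMask = matrix(TRUE, n, nch),
      meta = c(rec@meta, list(epoch_window = window,
                              dropped_events = dropped)))
}

#' Start a cleaning log for an epoched dataset
#'
#' @param ep an [EEGEpochs-class] fresh from [epochRecording()].
#' @return an empty [CleaningLog-class] carrying the original channel
#'   vocabulary and trial count.
#' @export
newCleaningLog <- function(ep) {
  new("CleaningLog",
      channels = ep@channelLabels, nTrials = nTrials(ep),
      removedChannels = data.frame(label = character(), step = integer(),
                                   stringsAsFactors = FALSE),
      removedTrials = data.frame(trial = integer(), step = integer()),
      removedCells = data.frame(channel = character(), trial = integer(),
                                step = integer(), stringsAsFactors = FALSE),
      filterParams = list(), icaSeed = NA_integer_,
      removedComponents = data.frame(component = integer(),
                                     label = character(),
                                     stringsAsFactors = FALSE),
      stepTimestamps = data.frame(step = integer(), time = character(),
                                  stringsAsFactors = FALSE))
}

#' Suggest gross-artifact removals (Step 2 / Step 6 auto mode)
#'
#' Flags (channel, trial) cells whose peak-to-peak amplitude exceeds
#' \code{ampThreshold}; promotes a channel or trial to whole removal when
#' its flagged-cell fraction exceeds \code{flaggedFraction}; and flags
#' channels whose variance exceeds \code{varMultiplier} times the median
#' channel variance, or is zero (flat/disconnected).
#'
#' @param ep an [EEGEpochs-class].
#' @param ampThreshold peak-to-peak limit, microvolts (default 150).
#' @param varMultiplier channel-variance multiple of the median (default 5).
#' @param flaggedFraction cell fraction promoting whole-channel/trial
#'   removal (default 0.5).
#' @return list(channels, trials, cells): labels, original trial indices,
#'   and data.frame(channel, trial) of residual cell flags.
#' @export
detectGrossArtifacts <- function(ep, ampThreshold = 150, varMultiplier = 5,
                                 flaggedFraction = 0.5) {
  if (ampThreshold <= 0 || varMultiplier <= 0)
    stop("configuration error: thresholds must be > 0", call. = FALSE)
  d <- ep@data
  n <- dim(d)[1]; nch <- dim(d)[2]
  ptp <- apply(d, c(1, 2), function(x) diff(range(x)))
  flagged <- ptp > ampThreshold & ep@cellMask

  chFrac <- colSums(flagged) / pmax(1, colSums(ep@cellMask))
  trFrac <- rowSums(flagged) / pmax(1, rowSums(ep@cellMask))
  badCh <- chFrac > flaggedFraction

  # robust (MAD-based) channel variance so one spiking trial cannot
  # promote a whole channel; zero variance = flat/disconnected
  chVar <- vapply(seq_len(nch), function(c)
    stats::mad(as.vector(d[, c, ][ep@cellMask[, c]]))^2, 0)
  badCh <- badCh | chVar > varMultiplier * stats::median(chVar) | chVar == 0
  badTr <- trFrac > flaggedFraction

  cells <- which(flagged, arr.ind = TRUE)
  keep <- !(badCh[cells[, 2]] | badTr[cells[, 1]])
  cells <- cells[keep, , drop = FALSE]
  list(channels = ep@channelLabels[badCh],
       trials = ep@trialIndices[badTr],
       cells = data.frame(channel = ep@channelLabels[cells[, 2]],
                          trial = ep@trialIndices[cells[, 1]],
                          stringsAsFactors = FALSE))
}

#' Apply channel/trial/cell removals with provenance (Steps 2 and 6)
#'
#' Removes whole channels and trials from the data and marks (channel,
#' trial) cells as missing in the cell mask, recording every removal in
#' the [CleaningLog-class] under the given step tag. Trials are addressed
#' by their original (pre-removal) indices throughout, so a saved log can
#' be replayed against the original epochs. Removing an index twice is a
#' consistency error.
#'
#' @param ep an [EEGEpochs-class].
#' @param log the dataset's [CleaningLog-class].
#' @param removals list(channels =, trials =, cells =) as produced by
#'   [detectGrossArtifacts()]; any element may be absent or empty.
#' @param step 2 or 6.
#' @return list(epochs, log).
#' @export
applyRejections <- function(ep, log, removals, step) {
  step <- as.integer(step)
  if (!step %in% c(2L, 6L))
    stop("step must be 2 or 6", call. = FALSE)
  ch <- unique(removals$channels %||% character())
  tr <- unique(removals$trials %||% integer())
  cells <- removals$cells %||% data.frame(channel = character(),
                                          trial = integer())

  if (length(bad <- setdiff(ch, ep@channelLabels)))
    stop("consistency error: channel(s) not present (already removed?): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(bad <- intersect(ch, log@removedChannels$label)))
    stop("consistency error: channel(s) removed twice: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(bad <- setdiff(tr, ep@trialIndices)))
    stop("consistency error: trial(s) not present (already removed?): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(cells)) {
    key <- paste(cells$channel, cells$trial)
    oldKey <- paste(log@removedCells$channel, log@removedCells$trial)
    if (any(key %in% oldKey))
      stop("consistency error: cell(s) removed twice", call. = FALSE)
    if (!all(cells$channel %in% ep@channelLabels) ||
        !all(cells$trial %in% ep@trialIndices))
      stop("consistency error: cell indices not present", call. = FALSE)
  }

  keepCh <- !(ep@channelLabels %in% ch)
  keepTr <- !(ep@trialIndices %in% tr)
  ep@data <- ep@data[keepTr, keepCh, , drop = FALSE]
  ep@cellMask <- ep@cellMask[keepTr, keepCh, drop = FALSE]
  ep@channelLabels <- ep@channelLabels[keepCh]
  ep@trialCodes <- ep@trialCodes[keepTr]
  ep@trialIndices <- ep@trialIndices[keepTr]
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      r <- match(cells$trial[i], ep@trialIndices)
      c <- match(cells$channel[i], ep@channelLabels)
      if (!is.na(r) && !is.na(c)) ep@cellMask[r, c] <- FALSE
    }
  }

  if (length(ch))
    log@removedChannels <- rbind(log@removedChannels,
                                 data.frame(label = ch, step = step,
                                            stringsAsFactors = FALSE))
  if (length(tr))
    log@removedTrials <- rbind(log@removedTrials,
                               data.frame(trial = tr, step = step))
  if (nrow(cells))
    log@removedCells <- rbind(log@removedCells,
                              data.frame(channel = cells$channel,
                                         trial = cells$trial, step = step,
                                         stringsAsFactors = FALSE))
  log@stepTimestamps <- rbind(log@stepTimestamps,
                              data.frame(step = step,
                                         time = format(Sys.time()),
                                         stringsAsFactors = FALSE))
  list(epochs = ep, log = log)
}

#' Surviving-data mask implied by a cleaning log
#'
#' Reconstructs, from the log alone, the original-frame trials x channels
#' logical mask of surviving cells: FALSE where the trial, the channel, or
#' the specific cell was removed.
#'
#' @param log a [CleaningLog-class].
#' @return logical matrix nTrials x nChannels (original frame), dimnames =
#'   trial index / channel label.
#' @export
survivingMask <- function(log) {
  m <- matrix(TRUE, log@nTrials, length(log@channels),
              dimnames = list(seq_len(log@nTrials), log@channels))
  if (nrow(log@removedTrials)) m[log@removedTrials$trial, ] <- FALSE
  if (nrow(log@removedChannels)) m[, log@removedChannels$label] <- FALSE
  if (nrow(log@removedCells))
    for (i in seq_len(nrow(log@removedCells)))
      m[log@removedCells$trial[i], log@removedCells$channel[i]] <- FALSE
  m
}

#' Surviving-data mask of an epoched dataset
#'
#' The actual original-frame mask of an [EEGEpochs-class] relative to the
#' original vocabulary in its log: used to verify provenance completeness
#' against [survivingMask()].
#'
#' @param ep an [EEGEpochs-class].
#' @param log the dataset's [CleaningLog-class] (supplies the original
#'   frame).
#' @return logical matrix as in [survivingMask()].
#' @export
currentMask <- function(ep, log) {
  m <- matrix(FALSE, log@nTrials, length(log@channels),
              dimnames = list(seq_len(log@nTrials), log@channels))
  m[ep@trialIndices, ep@channelLabels] <- ep@cellMask
  # channels reinstated by interpolation are reconstructions, not
  # surviving original data
  interp <- ep@meta$interpolated
  if (!is.null(interp)) m[, interp] <- FALSE
  m
}

#' Replay a cleaning log against the original epochs
#'
#' Applies all removals recorded in the log (in step order) to a fresh
#' epoching of the same data, reproducing the surviving-data state.
#'
#' @param ep the original (uncleaned) [EEGEpochs-class].
#' @param log a [CleaningLog-class] saved from a previous run.
#' @return list(epochs, log) with a freshly accumulated log equal in
#'   content to the input log's removal record.
#' @export
replayLog <- function(ep, log) {
  newLog <- newCleaningLog(ep)
  out <- list(epochs = ep, log = newLog)
  for (s in c(2L, 6L)) {
    rem <- list(
      channels = log@removedChannels$label[log@removedChannels$step == s],
      trials = log@removedTrials$trial[log@removedTrials$step == s],
      cells = log@removedCells[log@removedCells$step == s,
                               c("channel", "trial"), drop = FALSE])
    if (length(rem$channels) || length(rem$trials) || nrow(rem$cells))
      out <- applyRejections(out$epochs, out$log, rem, step = s)
  }
  out
}

#' Band-pass / notch filter epochs (Step 3)
#'
#' Zero-phase 4th-order Butterworth band-pass, with an optional band-stop
#' notch (+/- 2 Hz around the line frequency), applied per trial and
#' channel. Parameters are recorded in \code{meta$filterParams}.
#'
#' @param ep an [EEGEpochs-class].
#' @param band c(low, high) Hz, \code{0 <= low < high < rate/2}.
#' @param notch line frequency in Hz, or NULL.
#' @return filtered [EEGEpochs-class].
#' @export
filterEpochs <- function(ep, band, notch = NULL) {
  rate <- ep@samplingRate
  if (band[1] < 0 || band[1] >= band[2] || band[2] >= rate / 2)
    stop("configuration error: need 0 <= low < high < rate/2", call. = FALSE)
  d <- ep@data
  for (i in seq_len(dim(d)[1])) {
    x <- d[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, 1)
    x <- bandpassMatrix(x, rate, band[1], band[2])
    if (!is.null(notch))
      x <- butterZeroPhase(x, rate, low = notch - 2, high = notch + 2,
                           order = 2, type = "stop")
    d[i, , ] <- x
  }
  ep@data <- d
  ep@meta$filterParams <- list(band = band, notch = notch,
                               family = "butterworth", order = 4,
                               zero_phase = TRUE)
  ep
}

#' Average ERP across surviving trials
#'
#' Per-channel average over trials, honoring the cell mask (masked cells
#' are excluded from that channel's average).
#'
#' @param ep an [EEGEpochs-class].
#' @param codes optional subset of trial codes.
#' @return channels x samples matrix.
#' @export
averageErp <- function(ep, codes = NULL) {
  sel <- if (is.null(codes)) rep(TRUE, nTrials(ep)) else ep@trialCodes %in% codes
  d <- ep@data[sel, , , drop = FALSE]
  mask <- ep@cellMask[sel, , drop = FALSE]
  nch <- dim(d)[2]
  out <- matrix(0, nch, dim(d)[3],
                dimnames = list(ep@channelLabels, NULL))
  for (c in seq_len(nch)) {
    use <- mask[, c]
    if (any(use)) out[c, ] <- colMeans(d[use, c, , drop = FALSE][, 1, ])
  }
  out
}

#' Group-level cleaning summaries
#'
#' Aggregates a set of cleaning logs into the two standard summary
#' matrices: (1) mean number of trials removed per channel per group
#' (whole-trial removals count for every channel; cell removals count for
#' their channel), and (2) counts of removed components per artifact type
#' per dataset.
#'
#' @param logs list of [CleaningLog-class] objects sharing a channel
#'   vocabulary.
#' @param groups group label per log.
#' @return list(trialsPerChannel = channels x groups matrix,
#'   componentsPerDataset = type x dataset matrix).
#' @export
summarizeCleaning <- function(logs, groups) {
  if (!length(logs)) stop("empty-summary error: no logs supplied",
                          call. = FALSE)
  channels <- logs[[1]]@channels
  groups <- as.character(groups)
  glev <- unique(groups)
  counts <- matrix(0, length(channels), length(logs),
                   dimnames = list(channels, NULL))
  types <- c("blink", "eye-movement", "EMG", "ECG", "discontinuity", "other")
  comp <- matrix(0, length(types), length(logs),
                 dimnames = list(types, names(logs) %||%
                                   paste0("dataset", seq_along(logs))))
  for (k in seq_along(logs)) {
    lg <- logs[[k]]
    counts[, k] <- counts[, k] + nrow(lg@removedTrials)
    if (nrow(lg@removedCells)) {
      tab <- table(lg@removedCells$channel)
      counts[names(tab), k] <- counts[names(tab), k] + as.vector(tab)
    }
    if (nrow(lg@removedComponents)) {
      tab <- table(factor(lg@removedComponents$label, levels = types))
      comp[, k] <- as.vector(tab)
    }
  }
  trialsPerChannel <- vapply(glev, function(g)
    rowMeans(counts[, groups == g, drop = FALSE]),
    numeric(length(channels)))
  if (is.null(dim(trialsPerChannel)))
    trialsPerChannel <- matrix(trialsPerChannel, length(channels), 1,
                               dimnames = list(channels, glev))
  list(trialsPerChannel = trialsPerChannel, componentsPerDataset = comp)
}
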