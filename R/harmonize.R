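#' Match electrodes between two montages
#'
#' Maps every target electrode to its nearest source electrode by 3D
#' Euclidean distance on the unit-radius head frame. A source electrode may
#' serve several targets. Targets whose nearest source lies beyond
#' \code{maxDistance} are reported as unmatched. Exact distance ties are
#' broken toward the alphabetically smaller source label, so the mapping is
#' deterministic.
#'
#' @param source,target montages: data.frame(label, x, y, z).
#' @param maxDistance unit-frame length beyond which a target is unmatched
#'   (default 0.2).
#' @return a \code{"montageMap"}: list with \code{map} =
#'   data.frame(target, source, distance) and \code{unmatched} = character.
#' @export
matchElectrodes <- function(source, target, maxDistance = 0.2) {
  for (nm in c("source", "target")) {
    m <- get(nm)
    bad <- m$label[!stats::complete.cases(m[, c("x", "y", "z")])]
    if (length(bad))
      stop("montage error: missing positions for label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  sp <- as.matrix(source[, c("x", "y", "z")])
  tp <- as.matrix(target[, c("x", "y", "z")])
  ordSrc <- order(source$label)      # alphabetical tie-break
  sp <- sp[ordSrc, , drop = FALSE]
  slab <- source$label[ordSrc]
  map <- data.frame(target = character(), source = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  unmatched <- character()
  for (i in seq_len(nrow(tp))) {
    d <- sqrt(colSums((t(sp) - tp[i, ])^2))
    j <- which.min(d)                # first minimum = alphabetically smallest
    if (d[j] <= maxDistance) {
      map <- rbind(map, data.frame(target = target$label[i],
                                   source = slab[j], distance = d[j],
                                   stringsAsFactors = FALSE))
    } else {
      unmatched <- c(unmatched, target$label[i])
    }
  }
  structure(list(map = map, unmatched = unmatched), class = "montageMap")
}

#' Downsample a recording
#'
#' Anti-alias low-pass filters (zero-phase 4th-order Butterworth at 0.4 x
#' target rate) and polyphase-resamples the data to the target rate. Event
#' onsets are remapped to \code{round(onset * target / source)} with
#' round-half-to-even. Only downsampling is supported on the canonical
#' path; total duration is preserved within one output sample.
#'
#' @param rec an [EEGRecording-class].
#' @param targetRate Hz, \code{0 < targetRate <= samplingRate(rec)}.
#' @return resampled [EEGRecording-class].
#' @export
resampleRecording <- function(rec, targetRate) {
  if (!is.numeric(targetRate) || targetRate <= 0)
    stop("configuration error: targetRate must be > 0", call. = FALSE)
  src <- rec@samplingRate
  if (targetRate > src + 1e-9)
    stop("unsupported-upsample error: targetRate (", targetRate,
         ") exceeds source rate (", src, ")", call. = FALSE)
  if (abs(targetRate - src) < 1e-9) return(rec)

  nOut <- as.integer(round(ncol(rec@data) * targetRate / src))
  filtered <- butterZeroPhase(rec@data, src, high = 0.4 * targetRate,
                              type = "low")
  out <- matrix(0, nrow(filtered), nOut)
  for (i in seq_len(nrow(filtered)))
    out[i, ] <- fftResample(filtered[i, ], nOut)
  ev <- rec@events
  if (nrow(ev)) {
    ev$onset_sample <- as.integer(round(ev$onset_sample * targetRate / src))
    ev$onset_sample <- pmin(ev$onset_sample, nOut - 1L)
  }
  rec@data <- out
  rec@samplingRate <- targetRate
  rec@events <- ev
  rec@meta$resampled_from <- src
  rec
}

# Fourier-domain resampling to nOut samples: zero phase shift, output
# sample k lies exactly at time k/targetRate. The caller is expected to
# have low-pass filtered below the new Nyquist already.
fftResample <- function(x, nOut) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(nOut)
  nh <- min(n, nOut)
  npos <- ceiling(nh / 2)                 # DC + positive frequencies
  nneg <- floor((nh - 1) / 2)             # negative frequencies
  Y[seq_len(npos)] <- X[seq_len(npos)]
  if (nneg > 0)
    Y[nOut - seq_len(nneg) + 1] <- X[n - seq_len(nneg) + 1]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Re-reference a recording
#'
#' \code{"average"} subtracts the per-sample mean over included channels
#' (all channels minus \code{exclude}) from every channel; a channel label
#' (or pair of labels, for a linked reference) subtracts that channel's
#' signal (or the pair mean). Between-channel difference signals are
#' unaffected. The reference descriptor is updated.
#'
#' @param rec an [EEGRecording-class].
#' @param scheme \code{"average"}, a channel label, or two labels.
#' @param exclude labels excluded from the average.
#' @return re-referenced [EEGRecording-class].
#' @export
rereference <- function(rec, scheme, exclude = character()) {
  labs <- rec@channelLabels
  missing <- setdiff(exclude, labs)
  if (length(missing))
    stop("channel error: excluded label(s) not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(scheme) == 1 && scheme == "average") {
    incl <- setdiff(labs, exclude)
    ref <- colMeans(rec@data[match(incl, labs), , drop = FALSE])
    desc <- "average"
  } else {
    missing <- setdiff(scheme, labs)
    if (length(missing))
      stop("channel error: reference label(s) not present: ",
           paste(missing, collapse = ", "), call. = FALSE)
    ref <- colMeans(rec@data[match(scheme, labs), , drop = FALSE])
    desc <- paste(scheme, collapse = "-")
  }
  rec@data <- sweep(rec@data, 2, ref, "-")
  rec@reference <- desc
  rec
}

#' Stimulus-timing profile
#'
#' Summary of the event-marker timing delay of one acquisition setup: mean
#' and sd of (marked onset minus true onset) in milliseconds, and the
#' number of paired measurements behind the estimate.
#'
#' @param delayMean,delaySd ms; \code{delaySd >= 0}.
#' @param nMeasurements count, >= 1.
#' @param modality "auditory" or "visual".
#' @param setupDescription free-text description of the hardware setup.
#' @return list of class \code{"timingProfile"}.
#' @export
timingProfile <- function(delayMean, delaySd = 0, nMeasurements = 1L,
                          modality = "auditory", setupDescription = "") {
  if (delaySd < 0) stop("delaySd must be >= 0", call. = FALSE)
  if (nMeasurements < 1) stop("nMeasurements must be >= 1", call. = FALSE)
  structure(list(modality = modality, delayMean = delayMean,
                 delaySd = delaySd, nMeasurements = as.integer(nMeasurements),
                 setupDescription = setupDescription),
            class = "timingProfile")
}

#' Estimate the marker timing delay from paired onsets
#'
#' Given paired true and marked onsets (seconds, in order), computes the
#' delay as mean(marked - true) and its sample standard deviation, reported
#' in milliseconds as a [timingProfile()]. A positive delay means the
#' marker is late relative to the true stimulus (the convention of the
#' site simulator); [correctEventDelays()] undoes it.
#'
#' @param trueOnsets,markedOnsets equal-length numeric vectors, seconds.
#' @inheritParams timingProfile
#' @return a [timingProfile()].
#' @export
estimateDelay <- function(trueOnsets, markedOnsets, modality = "auditory",
                          setupDescription = "") {
  if (length(trueOnsets) != length(markedOnsets))
    stop("pairing error: onset lists must have equal length", call. = FALSE)
  if (length(trueOnsets) < 2)
    stop("pairing error: need at least 2 onset pairs", call. = FALSE)
  dMs <- (markedOnsets - trueOnsets) * 1000
  timingProfile(delayMean = mean(dMs), delaySd = stats::sd(dMs),
                nMeasurements = length(dMs), modality = modality,
                setupDescription = setupDescription)
}

#' Correct event-marker timing delays
#'
#' Shifts every event onset by \code{delaySign * delayMean} (rounded to the
#' nearest sample) so markers land on the true stimulus onsets. With the
#' estimator of [estimateDelay()] (delay = marked - true, positive = marker
#' late) the correction subtracts the delay, hence the default
#' \code{delaySign = -1}; the flag accommodates setups whose measured delay
#' is reported with the opposite sign. Onsets that would leave the
#' recording are clipped and reported via a boundary warning and in
#' \code{meta}.
#'
#' @param rec an [EEGRecording-class].
#' @param profile a [timingProfile()].
#' @param delaySign +1 or -1; see Details.
#' @return corrected [EEGRecording-class]; the applied shift is recorded in
#'   \code{meta$delay_correction}.
#' @export
correctEventDelays <- function(rec, profile, delaySign = -1) {
  stopifnot(inherits(profile, "timingProfile"))
  if (!is.finite(profile$delayMean))
    stop("profile delayMean must be finite", call. = FALSE)
  rate <- rec@samplingRate
  shift <- delaySign * profile$delayMean / 1000 * rate
  ev <- rec@events
  clipped <- integer()
  if (nrow(ev)) {
    newOn <- round(ev$onset_sample + shift)
    low <- newOn < 0
    high <- newOn > ncol(rec@data) - 1
    clipped <- which(low | high)
    if (length(clipped))
      warning("boundary warning: ", length(clipped),
              " event(s) clipped by delay correction: ",
              paste(clipped, collapse = ", "))
    newOn[low] <- 0
    newOn[high] <- ncol(rec@data) - 1
    ev$onset_sample <- as.integer(newOn)
    ev <- ev[order(ev$onset_sample), , drop = FALSE]
    rownames(ev) <- NULL
    rec@events <- ev
  }
  rec@meta$delay_correction <- list(delay_ms = profile$delayMean,
                                    sign = delaySign,
                                    clipped_events = clipped)
  rec
}

#' Canonical acquisition specification
#'
#' The common form all site recordings are converted to: target sampling
#' rate, target channel set with positions, target reference, pass band,
#' and the maximum electrode-matching distance. Per the lower-boundary
#' strategy, the target rate/channel count should be those of the most
#' limited site.
#'
#' @param targetRate Hz, > 0.
#' @param targetChannels montage data.frame(label, x, y, z).
#' @param targetReference reference descriptor.
#' @param bandwidth c(low, high) Hz with \code{low < high < targetRate/2}.
#' @param maxMatchDistance unit-frame electrode matching radius.
#' @return list of class \code{"canonicalSpec"}.
#' @export
canonicalSpec <- function(targetRate, targetChannels,
                          targetReference = "average",
                          bandwidth = c(0.5, 55),
                          maxMatchDistance = 0.2) {
  if (targetRate <= 0)
    stop("configuration error: targetRate must be > 0", call. = FALSE)
  if (!(bandwidth[1] < bandwidth[2] && bandwidth[2] < targetRate / 2))
    stop("configuration error: need bandwidth low < high < targetRate/2",
         call. = FALSE)
  structure(list(targetRate = targetRate, targetChannels = targetChannels,
                 targetReference = targetReference, bandwidth = bandwidth,
                 maxMatchDistance = maxMatchDistance),
            class = "canonicalSpec")
}

#' Harmonize a site recording to the canonical form
#'
#' Applies, in fixed order: (1) marker delay correction (when a timing
#' profile is supplied), (2) electrode matching and renaming to the target
#' channel set, (3) band-pass filtering to the canonical bandwidth,
#' (4) resampling to the target rate, (5) re-referencing to the target
#' reference. The output satisfies all five canonical properties (rate,
#' bandwidth, channels, reference, event matrix on the target clock); the
#' full parameter record, including unmatched target channels, is appended
#' to \code{meta$harmonization}.
#'
#' Electrode matching uses positions when the recording carries them and
#' falls back to label identity otherwise.
#'
#' @param rec an [EEGRecording-class].
#' @param spec a [canonicalSpec()].
#' @param profile optional [timingProfile()] for marker delay correction.
#' @param delaySign see [correctEventDelays()].
#' @return harmonized [EEGRecording-class].
#' @export
harmonizeRecording <- function(rec, spec, profile = NULL, delaySign = -1) {
  stopifnot(inherits(spec, "canonicalSpec"))
  step <- "delay-correction"
  out <- tryCatch({
    if (!is.null(profile)) rec <- correctEventDelays(rec, profile, delaySign)

    step <- "channel-matching"
    tgt <- spec$targetChannels
    if (nrow(rec@channelPositions) > 0) {
      srcMontage <- data.frame(label = rec@channelLabels,
                               rec@channelPositions[rec@channelLabels, ,
                                                    drop = FALSE],
                               stringsAsFactors = FALSE)
      mm <- matchElectrodes(srcMontage, tgt, spec$maxMatchDistance)
    } else {
      found <- tgt$label[tgt$label %in% rec@channelLabels]
      mm <- structure(list(
        map = data.frame(target = found, source = found,
                         distance = 0, stringsAsFactors = FALSE),
        unmatched = setdiff(tgt$label, rec@channelLabels)),
        class = "montageMap")
    }
    rec@data <- rec@data[match(mm$map$source, rec@channelLabels), ,
                         drop = FALSE]
    rec@channelLabels <- mm$map$target
    rec@channelPositions <- as.positions(
      tgt[match(mm$map$target, tgt$label), , drop = FALSE])

    step <- "band-pass"
    # already harmonized to this band once -> do not filter again, so
    # harmonization is idempotent instead of compounding attenuation
    alreadyBanded <- identical(rec@meta$harmonization$bandwidth,
                               spec$bandwidth)
    if (!alreadyBanded)
      rec@data <- bandpassMatrix(rec@data, rec@samplingRate,
                                 spec$bandwidth[1], spec$bandwidth[2])

    step <- "resample"
    rec <- resampleRecording(rec, spec$targetRate)

    step <- "re-reference"
    rec <- rereference(rec, spec$targetReference)

    rec@meta$harmonization <- list(
      target_rate = spec$targetRate,
      bandwidth = spec$bandwidth,
      reference = spec$targetReference,
      matched = mm$map, unmatched = mm$unmatched,
      delay_profile = if (is.null(profile)) NULL else unclass(profile),
      delay_sign = if (is.null(profile)) NULL else delaySign)
    rec
  }, error = function(e) {
    stop("harmonization failed at step '", step, "': ",
         conditionMessage(e), call. = FALSE)
  })
  out
}
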