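#' Configuration for the synthetic multi-site ERP generator
#'
#' Builds and validates the configuration for [genRecording()]. The
#' generator composes band-limited oscillations, pink (1/f power) background
#' noise, an injected ERP component time-locked to every event, and
#' optional artifact classes (blinks, EMG bursts, line noise, a flat
#' channel), on a chosen montage. All ingredients are recorded in the
#' returned ground truth, so downstream modules can be tested against a
#' known answer.
#'
#' @param nChannels number of channels; must match \code{montage} rows.
#' @param samplingRate Hz, > 0.
#' @param duration seconds, > 0.
#' @param oscillations list of \code{list(freq, amplitude, weights)}
#'   entries; \code{weights} is a per-channel vector (default all 1).
#' @param erp \code{list(latency, amplitude, width, topography, code)}:
#'   a Gaussian-envelope component of peak \code{amplitude} microvolts at
#'   \code{latency} seconds after each event, envelope sd
#'   \code{width / 2}; \code{topography} is a per-channel weight vector
#'   (default: centro-parietal falloff from the vertex).
#' @param artifacts \code{list(blinkRate, blinkAmplitude, emgRate, emgBand,
#'   emgAmplitude, lineFreq, lineAmplitude, flatChannel)}; rates are events
#'   per minute; \code{flatChannel} is a channel index or label, NULL for
#'   none.
#' @param noise pink-noise standard deviation in microvolts.
#' @param nEvents number of stimulus events.
#' @param interStimulusInterval seconds between events; must exceed
#'   \code{erp$latency + erp$width}.
#' @param seed integer seed; the generator is bit-deterministic given the
#'   config and seed.
#' @param montage data.frame(label, x, y, z); default [montage1020()]
#'   (or a Fibonacci layout when \code{nChannels != 19}).
#' @return validated config list of class \code{"synthConfig"}.
#' @export
synthConfig <- function(nChannels = 19, samplingRate = 500, duration = 60,
                        oscillations = list(list(freq = 10, amplitude = 3,
                                                 weights = NULL)),
                        erp = list(latency = 0.3, amplitude = 8, width = 0.1,
                                   topography = NULL, code = 1L),
                        artifacts = list(), noise = 5,
                        nEvents = 30, interStimulusInterval = 1.5,
                        seed = 1L, montage = NULL) {
  bad <- function(field, why) stop("invalid configuration field '", field,
                                   "': ", why, call. = FALSE)
  if (!is.numeric(samplingRate) || samplingRate <= 0)
    bad("samplingRate", "must be > 0")
  if (!is.numeric(duration) || duration <= 0) bad("duration", "must be > 0")
  if (!is.numeric(noise) || noise < 0) bad("noise", "must be >= 0")
  if (nChannels < 1) bad("nChannels", "must be >= 1")
  if (is.null(montage))
    montage <- if (nChannels == 19) montage1020() else fibonacciMontage(nChannels)
  if (nrow(montage) != nChannels)
    bad("montage", "row count must equal nChannels")

  erp <- utils::modifyList(list(latency = 0.3, amplitude = 8, width = 0.1,
                                topography = NULL, code = 1L), erp)
  if (erp$amplitude < 0) bad("erp.amplitude", "must be >= 0")
  if (erp$latency < 0) bad("erp.latency", "must be >= 0")
  if (erp$width <= 0) bad("erp.width", "must be > 0")
  if (erp$latency + erp$width >= interStimulusInterval)
    bad("erp", "latency + width must be < interStimulusInterval")
  if (is.null(erp$topography)) {
    # centro-parietal falloff from the vertex electrode
    pos <- as.positions(montage)
    d2 <- rowSums(sweep(pos, 2, c(0, -0.3, 0.95), "-")^2)
    erp$topography <- exp(-d2 / 0.5)
  }
  if (length(erp$topography) != nChannels)
    bad("erp.topography", "length must equal nChannels")

  for (i in seq_along(oscillations)) {
    o <- utils::modifyList(list(freq = 10, amplitude = 1, weights = NULL),
                           oscillations[[i]])
    if (o$amplitude < 0) bad("oscillations.amplitude", "must be >= 0")
    if (o$freq <= 0 || o$freq >= samplingRate / 2)
      bad("oscillations.freq", "must lie in (0, samplingRate/2)")
    if (is.null(o$weights)) o$weights <- rep(1, nChannels)
    if (length(o$weights) != nChannels)
      bad("oscillations.weights", "length must equal nChannels")
    oscillations[[i]] <- o
  }

  artifacts <- utils::modifyList(
    list(blinkRate = 0, blinkAmplitude = 120, blinkDuration = 0.3,
         emgRate = 0, emgBand = c(20, 100), emgAmplitude = 30,
         emgDuration = 0.5, lineFreq = NULL, lineAmplitude = 2,
         flatChannel = NULL), artifacts)
  for (f in c("blinkRate", "blinkAmplitude", "emgRate", "emgAmplitude",
              "lineAmplitude"))
    if (artifacts[[f]] < 0) bad(paste0("artifacts.", f), "must be >= 0")

  if (nEvents >= 1 &&
      1 + nEvents * interStimulusInterval > duration)
    bad("nEvents", "events do not fit in duration at the given interval")

  structure(list(nChannels = nChannels, samplingRate = samplingRate,
                 duration = duration, oscillations = oscillations, erp = erp,
                 artifacts = artifacts, noise = noise, nEvents = nEvents,
                 interStimulusInterval = interStimulusInterval,
                 seed = as.integer(seed), montage = montage),
            class = "synthConfig")
}

#' The ERP waveform injected by the generator
#'
#' Evaluates the injected ERP component on a time axis (0 = event onset):
#' a Gaussian envelope of sd \code{width/2} peaking at \code{latency}.
#'
#' @param erp the \code{erp} element of a [synthConfig()].
#' @param tAxis time axis in seconds.
#' @return numeric vector, microvolts (unit topography weight).
#' @export
erpWaveform <- function(erp, tAxis) {
  erp$amplitude * exp(-(tAxis - erp$latency)^2 / (2 * (erp$width / 2)^2))
}

#' Generate a synthetic ERP recording with ground truth
#'
#' Deterministically (per seed) synthesizes a continuous multichannel EEG
#' recording: pink background noise + oscillations + an ERP component
#' locked to each event + configured artifacts. The returned event matrix
#' holds the TRUE stimulus onsets; site-specific marker delays are applied
#' separately by [applySite()].
#'
#' @param config a [synthConfig()].
#' @return \code{list(recording, truth)}: an [EEGRecording-class] and a
#'   ground-truth list with elements \code{true_event_onsets} (seconds),
#'   \code{injected_erp}, \code{artifact_intervals} (per kind:
#'   data.frame(channel, start, end)), \code{site_params} (NULL until
#'   [applySite()]).
#' @export
genRecording <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  set.seed(config$seed)
  rate <- config$samplingRate
  nsamp <- round(config$duration * rate)
  nch <- config$nChannels
  tt <- (seq_len(nsamp) - 1) / rate
  labels <- config$montage$label
  pos <- as.positions(config$montage)

  data <- matrix(0, nch, nsamp)
  if (config$noise > 0)
    for (i in seq_len(nch)) data[i, ] <- pinkNoise(nsamp, config$noise)

  for (o in config$oscillations) {
    if (o$amplitude == 0) next
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- o$amplitude * sin(2 * pi * o$freq * tt + phase)
    data <- data + outer(o$weights, wave)
  }

  # events on a regular grid starting 1 s in; onsets are exact samples
  onsets <- integer(0)
  if (config$nEvents >= 1) {
    onsetSec <- 1 + (seq_len(config$nEvents) - 1) * config$interStimulusInterval
    onsets <- as.integer(round(onsetSec * rate))
  }
  erp <- config$erp
  if (length(onsets) && erp$amplitude > 0) {
    span <- round((erp$latency + 4 * erp$width) * rate)
    wav <- erpWaveform(erp, (0:span) / rate)
    for (on in onsets) {
      idx <- (on + 1):(on + 1 + span)
      keep <- idx <= nsamp
      data[, idx[keep]] <- data[, idx[keep]] + outer(erp$topography, wav[keep])
    }
  }

  art <- config$artifacts
  intervals <- list()
  frontalW <- exp(-rowSums(sweep(pos, 2, c(0, 0.95, 0.2), "-")^2) / 0.25)
  if (art$blinkRate > 0) {
    nBlink <- max(1L, round(art$blinkRate * config$duration / 60))
    starts <- sort(stats::runif(nBlink, 0, config$duration - art$blinkDuration))
    blinkLen <- round(art$blinkDuration * rate)
    halfSine <- sin(pi * (0:(blinkLen - 1)) / (blinkLen - 1))
    rows <- lapply(starts, function(s) {
      i0 <- round(s * rate) + 1
      idx <- i0:(i0 + blinkLen - 1)
      data[, idx] <<- data[, idx] +
        outer(frontalW * art$blinkAmplitude, halfSine)
      data.frame(channel = labels[which.max(frontalW)], start = s,
                 end = s + art$blinkDuration)
    })
    intervals$blink <- do.call(rbind, rows)
  }
  if (art$emgRate > 0) {
    nBurst <- max(1L, round(art$emgRate * config$duration / 60))
    starts <- sort(stats::runif(nBurst, 0, config$duration - art$emgDuration))
    burstLen <- round(art$emgDuration * rate)
    hi <- min(art$emgBand[2], 0.45 * rate)
    rows <- lapply(starts, function(s) {
      ch <- sample(nch, 1)
      i0 <- round(s * rate) + 1
      burst <- stats::rnorm(burstLen)
      burst <- bandpassMatrix(matrix(burst, 1), rate, art$emgBand[1], hi)[1, ]
      burst <- burst / stats::sd(burst) * art$emgAmplitude
      taper <- sin(pi * (0:(burstLen - 1)) / (burstLen - 1))
      data[ch, i0:(i0 + burstLen - 1)] <<-
        data[ch, i0:(i0 + burstLen - 1)] + burst * taper
      data.frame(channel = labels[ch], start = s, end = s + art$emgDuration)
    })
    intervals$emg <- do.call(rbind, rows)
  }
  if (!is.null(art$lineFreq) && art$lineAmplitude > 0) {
    line <- art$lineAmplitude * sin(2 * pi * art$lineFreq * tt)
    data <- data + matrix(line, nch, nsamp, byrow = TRUE)
    intervals$line <- data.frame(channel = NA_character_, start = 0,
                                 end = config$duration)
  }
  if (!is.null(art$flatChannel)) {
    fc <- art$flatChannel
    if (is.character(fc)) fc <- match(fc, labels)
    data[fc, ] <- 0
    intervals$flat <- data.frame(channel = labels[fc], start = 0,
                                 end = config$duration)
  }

  events <- if (length(onsets)) makeEvents(onsets, erp$code) else emptyEvents()
  rec <- newRecording(
    id = sprintf("synth-seed%d", config$seed), data = data,
    samplingRate = rate, channelLabels = labels, channelPositions = pos,
    reference = "average", events = events,
    meta = list(site = "synthetic", task = "erp", visit = "01",
                generator_seed = config$seed))
  truth <- list(true_event_onsets = onsets / rate,
                injected_erp = erp,
                artifact_intervals = intervals,
                site_params = NULL,
                confound_offsets = NULL)
  list(recording = rec, truth = truth)
}

#' Site specification for multi-site simulation
#'
#' Describes one acquisition site: sampling rate, montage subset,
#' reference scheme, and the stimulus-marker delay model — a Normal
#' per-trial delay (mean, sd, in ms) plus a per-trial linear drift
#' (accumulating timing error over sequential trials, in ms/trial).
#'
#' @param siteId site identifier.
#' @param samplingRate Hz.
#' @param montage data.frame(label, x, y, z); must be a subset of the
#'   recording's channels when applied.
#' @param reference reference descriptor.
#' @param delayMean,delaySd marker delay distribution, ms; \code{delaySd
#'   >= 0}.
#' @param driftPerTrial additional delay accumulated per sequential trial,
#'   ms.
#' @return validated list of class \code{"siteSpec"}.
#' @export
siteSpec <- function(siteId, samplingRate, montage, reference = "average",
                     delayMean = 0, delaySd = 0, driftPerTrial = 0) {
  if (delaySd < 0) stop("invalid configuration field 'delaySd': must be >= 0",
                        call. = FALSE)
  if (anyDuplicated(montage$label))
    stop("invalid configuration field 'montage': labels must be unique",
         call. = FALSE)
  structure(list(siteId = siteId, samplingRate = samplingRate,
                 montage = montage, reference = reference,
                 delayMean = delayMean, delaySd = delaySd,
                 driftPerTrial = driftPerTrial), class = "siteSpec")
}

#' Render a ground-truth recording as acquired at a site
#'
#' Restricts the recording to the site montage, re-references per the site
#' scheme, resamples to the site rate, and replaces the event matrix with
#' MARKED onsets: each marked onset is the true onset plus a delay drawn
#' from Normal(delayMean, delaySd) plus \code{trialIndex * driftPerTrial}
#' (ms), rounded to the nearest sample. When the site matches the
#' recording's rate/montage/reference and all delays are zero, the data
#' pass through untouched.
#'
#' @param rec an [EEGRecording-class] (events at true onsets).
#' @param truth ground truth from [genRecording()].
#' @param site a [siteSpec()].
#' @param seed integer seed for the delay draws.
#' @return \code{list(recording, truth)} with \code{truth$site_params} set.
#' @export
applySite <- function(rec, truth, site, seed = 1L) {
  stopifnot(inherits(site, "siteSpec"))
  missing <- setdiff(site$montage$label, rec@channelLabels)
  if (length(missing))
    stop("montage mapping error: label(s) absent from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)

  out <- rec
  if (!identical(sort(site$montage$label), sort(out@channelLabels)) ||
      !identical(site$montage$label, out@channelLabels)) {
    keep <- match(site$montage$label, out@channelLabels)
    if (!identical(keep, seq_len(nChannels(out)))) {
      out@data <- out@data[keep, , drop = FALSE]
      out@channelLabels <- out@channelLabels[keep]
    }
  }
  out@channelPositions <- as.positions(site$montage)
  if (!identical(site$reference, out@reference))
    out <- rereference(out, site$reference)
  if (abs(site$samplingRate - out@samplingRate) > 1e-9)
    out <- resampleRecording(out, site$samplingRate)

  rate <- out@samplingRate
  trueOn <- truth$true_event_onsets
  nEv <- length(trueOn)
  set.seed(seed)
  delayMs <- stats::rnorm(nEv, site$delayMean, site$delaySd) +
    (seq_len(nEv) - 1) * site$driftPerTrial
  marked <- as.integer(round(trueOn * rate + delayMs / 1000 * rate))
  marked <- pmax(0L, pmin(marked, nSamples(out) - 1L))
  if (nEv) {
    out@events <- makeEvents(marked, out@events$code, out@events$label)
  }
  out@id <- paste0(rec@id, "-", site$siteId)
  out@meta$site <- site$siteId
  truth$site_params <- site
  list(recording = out, truth = truth)
}

#' Generate a subject-clustered feature table
#'
#' Emulates per-record EEG feature vectors with the subject-level structure
#' that makes record-wise cross-validation leak: every subject receives a
#' persistent random offset (sd \code{confoundSd}) added to all of its
#' records, labels are assigned per subject (balanced), and a genuine class
#' effect of standardized size \code{effectSize} is placed on feature 1.
#' Record-level noise is standard normal.
#'
#' @param nSubjects even count, >= 2.
#' @param recordsPerSubject records per subject, >= 1.
#' @param nFeatures feature dimensionality.
#' @param effectSize standardized class difference on feature 1.
#' @param confoundSd sd of the per-subject offset applied to every feature.
#' @param seed integer seed.
#' @return \code{list(table, truth)}: the feature table
#'   data.frame(subject_id, record_id, label, f1..fk) and ground truth with
#'   \code{confound_offsets} (subjects x features) and the effect size.
#' @export
genFeatureTable <- function(nSubjects, recordsPerSubject, nFeatures = 20,
                            effectSize = 0, confoundSd = 0, seed = 1L) {
  if (nSubjects < 2)
    stop("invalid configuration field 'nSubjects': must be >= 2", call. = FALSE)
  if (nSubjects %% 2 != 0)
    stop("invalid configuration field 'nSubjects': balanced labels require ",
         "an even subject count", call. = FALSE)
  if (recordsPerSubject < 1)
    stop("invalid configuration field 'recordsPerSubject': must be >= 1",
         call. = FALSE)
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(nSubjects))
  labels <- sample(rep(c("A", "B"), nSubjects / 2))
  offsets <- matrix(stats::rnorm(nSubjects * nFeatures, 0, confoundSd),
                    nSubjects, nFeatures, dimnames = list(subj, NULL))
  rows <- lapply(seq_len(nSubjects), function(s) {
    n <- recordsPerSubject
    feat <- matrix(stats::rnorm(n * nFeatures), n, nFeatures)
    feat <- sweep(feat, 2, offsets[s, ], "+")
    feat[, 1] <- feat[, 1] + ifelse(labels[s] == "A", 1, -1) * effectSize / 2
    cbind(data.frame(subject_id = subj[s],
                     record_id = sprintf("%s_r%02d", subj[s], seq_len(n)),
                     label = labels[s], stringsAsFactors = FALSE),
          as.data.frame(feat))
  })
  tab <- do.call(rbind, rows)
  names(tab)[-(1:3)] <- paste0("f", seq_len(nFeatures))
  rownames(tab) <- NULL
  truth <- list(confound_offsets = offsets, effect_size = effectSize,
                labels = stats::setNames(labels, subj))
  list(table = tab, truth = truth)
}

#' Serialize / load ground truth
#'
#' Ground truth is written as JSON alongside every generated file so
#' acceptance checks can recover the injected signal without rerunning the
#' generator.
#'
#' @param truth ground-truth list.
#' @param path file path.
#' @return \code{readGroundTruth}: the list; writer returns path invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  truth$site_params <- unclass(truth$site_params)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
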