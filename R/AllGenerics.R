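#' @include AllClasses.R
NULL

#' Accessors for EEG containers
#'
#' Standard accessors for [EEGRecording-class] and [EEGEpochs-class]:
#' sampling rate (Hz), channel labels, electrode positions, the event
#' matrix, the signal data and basic dimensions.
#'
#' @param x an \code{EEGRecording} or \code{EEGEpochs} object.
#' @return \code{samplingRate}: Hz; \code{channelLabels}: character;
#'   \code{channelPositions}: matrix with columns x, y, z;
#'   \code{eventTable}: data.frame(onset_sample, code, label);
#'   \code{signalData}: the data matrix/array; \code{nChannels},
#'   \code{nSamples}, \code{nTrials}: integer counts; \code{timeAxis}:
#'   seconds; \code{trialCodes}: integer codes; \code{referenceScheme}:
#'   reference descriptor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("trialCodes", function(x) standardGeneric("trialCodes"))
#' @rdname accessors
#' @export
setGeneric("referenceScheme", function(x) standardGeneric("referenceScheme"))
#' @rdname accessors
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "EEGEpochs", function(x) x@samplingRate)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "EEGEpochs", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelPositions", "EEGRecording", function(x) x@channelPositions)
#' @rdname accessors
setMethod("channelPositions", "EEGEpochs", function(x) x@channelPositions)
#' @rdname accessors
setMethod("eventTable", "EEGRecording", function(x) x@events)
#' @rdname accessors
setMethod("signalData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("signalData", "EEGEpochs", function(x) x@data)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "EEGEpochs", function(x) dim(x@data)[2])
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nSamples", "EEGEpochs", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("nTrials", "EEGEpochs", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("timeAxis", "EEGEpochs", function(x) x@timeAxis)
#' @rdname accessors
setMethod("trialCodes", "EEGEpochs", function(x) x@trialCodes)
#' @rdname accessors
setMethod("referenceScheme", "EEGRecording", function(x) x@reference)
#' @rdname accessors
setMethod("referenceScheme", "EEGEpochs", function(x) x@reference)
#' @rdname accessors
setMethod("recordingMeta", "EEGRecording", function(x) x@meta)
#' @rdname accessors
setMethod("recordingMeta", "EEGEpochs", function(x) x@meta)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording \"%s\": %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@id, nChannels(object), nSamples(object),
              object@samplingRate, nSamples(object) / object@samplingRate))
  cat(sprintf("  reference: %s; events: %d; positions: %s\n",
              object@reference, nrow(object@events),
              if (nrow(object@channelPositions)) "yes" else "no"))
  invisible(object)
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGEpochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@samplingRate))
  cat(sprintf("  window: [%.3f, %.3f] s; masked cells: %d\n",
              min(object@timeAxis), max(object@timeAxis),
              sum(!object@cellMask)))
  invisible(object)
})

setMethod("show", "CleaningLog", function(object) {
  cat(sprintf(
    "CleaningLog: %d/%d channels, %d/%d trials, %d cells, %d components removed\n",
    nrow(object@removedChannels), length(object@channels),
    nrow(object@removedTrials), object@nTrials,
    nrow(object@removedCells), nrow(object@removedComponents)))
  invisible(object)
})

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition (%s): %d components on %d channels, seed %d\n",
              object@algorithm, ncol(object@mixing),
              nrow(object@mixing), object@seed))
  invisible(object)
})

setMethod("show", "StepArchive", function(object) {
  cat(sprintf("StepArchive: %d step(s) in %s\n",
              nrow(object@records), object@dir))
  if (nrow(object@records))
    print(object@records[, c("step", "name")], row.names = FALSE)
  invisible(object)
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: %s grid [%s], df = %g, tail = %s\n",
              paste(object@dimNames, collapse = " x "),
              paste(dim(object@values), collapse = " x "),
              object@df, object@tail))
  invisible(object)
})

setMethod("show", "Adjacency", function(object) {
  cat(sprintf("Adjacency over %s grid (%s): %d edges\n",
              paste(object@shape, collapse = " x "), object@descriptor,
              sum(lengths(object@neighbors)) / 2))
  invisible(object)
})
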