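#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Central container for a continuous EEG recording: a channels-by-samples
#' data matrix in microvolts, channel labels and (optionally) 3D electrode
#' positions on a unit-radius head frame, the reference descriptor, an event
#' matrix of stimulus markers, and free-form acquisition metadata (site,
#' task, visit, operator notes, processing history).
#'
#' The event matrix is a \code{data.frame} with columns \code{onset_sample}
#' (0-based integer sample index), \code{code} (integer) and \code{label}
#' (character). Onsets must be nondecreasing and lie within
#' \code{[0, nSamples)}.
#'
#' @slot id recording identifier.
#' @slot samplingRate sampling rate in Hz.
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot channelLabels unique channel labels, one per data row.
#' @slot channelPositions numeric matrix with columns x, y, z and one row per
#'   labelled electrode (rownames are labels); may have zero rows when
#'   positions are unknown.
#' @slot reference reference descriptor: a channel label, \code{"average"},
#'   \code{"linked-mastoids"} or \code{"unknown"}.
#' @slot events event matrix (see Details).
#' @slot meta named list of acquisition annotations.
#'
#' @seealso [newRecording()], [genRecording()], [harmonizeRecording()]
#' @export
setClass("EEGRecording",
  representation(
    id = "character",
    samplingRate = "numeric",
    data = "matrix",
    channelLabels = "character",
    channelPositions = "matrix",
    reference = "character",
    events = "data.frame",
    meta = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data row count must equal number of channel labels")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@channelPositions) > 0) {
    if (ncol(object@channelPositions) != 3L)
      msg <- c(msg, "channelPositions must have 3 columns (x, y, z)")
    if (!all(rownames(object@channelPositions) %in% object@channelLabels))
      msg <- c(msg, "channelPositions rownames must be channel labels")
  }
  ev <- object@events
  need <- c("onset_sample", "code", "label")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, "events must have columns onset_sample, code, label")
  } else if (nrow(ev) > 0) {
    if (any(ev$onset_sample < 0) || any(ev$onset_sample >= ncol(object@data)))
      msg <- c(msg, "event onsets must lie within [0, nSamples)")
    if (is.unsorted(ev$onset_sample))
      msg <- c(msg, "event onsets must be nondecreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Trial-segmented EEG epochs
#'
#' Epoched data extracted around event onsets: a trials x channels x samples
#' array with a time axis whose zero is the event onset. Cell-level removals
#' (a single trial on a single channel) are tracked in \code{cellMask}
#' rather than by deleting data, so the surviving-data mask is always
#' reconstructable.
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot timeAxis time in seconds relative to event onset, uniform step.
#' @slot trialCodes integer event code per trial.
#' @slot trialIndices original trial numbers (1-based) before any removal,
#'   used by the provenance log.
#' @slot channelLabels,channelPositions,samplingRate,reference as in
#'   [EEGRecording-class].
#' @slot cellMask logical trials x channels matrix; \code{TRUE} = cell
#'   present, \code{FALSE} = removed at cell level.
#' @slot meta named list (records the epoching window, dropped edge events,
#'   and pipeline parameters).
#'
#' @seealso [epochRecording()], [runPipeline()]
#' @export
setClass("EEGEpochs",
  representation(
    data = "array",
    timeAxis = "numeric",
    trialCodes = "integer",
    trialIndices = "integer",
    channelLabels = "character",
    channelPositions = "matrix",
    samplingRate = "numeric",
    reference = "character",
    cellMask = "matrix",
    meta = "list"
  )
)

setValidity("EEGEpochs", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channel dimension must match channelLabels")
    if (d[1] != length(object@trialCodes))
      msg <- c(msg, "trialCodes length must equal number of trials")
    if (d[1] != length(object@trialIndices))
      msg <- c(msg, "trialIndices length must equal number of trials")
    if (d[3] != length(object@timeAxis))
      msg <- c(msg, "timeAxis length must equal number of samples")
    if (!all(dim(object@cellMask) == d[1:2]))
      msg <- c(msg, "cellMask must be trials x channels")
  }
  if (length(object@timeAxis) > 1) {
    step <- diff(object@timeAxis)
    if (any(step <= 0))
      msg <- c(msg, "timeAxis must be strictly increasing")
    if (max(abs(step - 1 / object@samplingRate)) > 1e-9)
      msg <- c(msg, "timeAxis step must equal 1/samplingRate")
  }
  if (length(msg)) msg else TRUE
})

#' Replayable cleaning provenance log
#'
#' Complete record of every removal performed while cleaning an epoched
#' dataset: channels, trials and (channel, trial) cells with the pipeline
#' step (2, 5 or 6) at which each was removed, filter parameters, the ICA
#' seed and the removed components with their artifact labels. Together
#' with the original trial/channel vocabulary this is sufficient to replay
#' the cleaning on the raw epochs and reproduce the surviving-data mask
#' exactly.
#'
#' @slot channels original channel vocabulary.
#' @slot nTrials original trial count.
#' @slot removedChannels data.frame(label, step).
#' @slot removedTrials data.frame(trial, step); original 1-based trial ids.
#' @slot removedCells data.frame(channel, trial, step).
#' @slot filterParams list (band, notch, filter family/order) or empty.
#' @slot icaSeed integer seed used for the ICA decomposition (NA before
#'   step 4).
#' @slot removedComponents data.frame(component, label) with label one of
#'   blink, eye-movement, EMG, ECG, discontinuity, other.
#' @slot stepTimestamps data.frame(step, time).
#'
#' @seealso [applyRejections()], [replayLog()], [summarizeCleaning()]
#' @export
setClass("CleaningLog",
  representation(
    channels = "character",
    nTrials = "integer",
    removedChannels = "data.frame",
    removedTrials = "data.frame",
    removedCells = "data.frame",
    filterParams = "list",
    icaSeed = "integer",
    removedComponents = "data.frame",
    stepTimestamps = "data.frame"
  )
)

setValidity("CleaningLog", function(object) {
  msg <- character()
  okStep <- function(s) all(s %in% c(2L, 5L, 6L))
  if (nrow(object@removedChannels) &&
      (!okStep(object@removedChannels$step) ||
       anyDuplicated(object@removedChannels$label)))
    msg <- c(msg, "removedChannels: step must be 2/5/6 and labels unique")
  if (nrow(object@removedTrials) &&
      (!okStep(object@removedTrials$step) ||
       anyDuplicated(object@removedTrials$trial)))
    msg <- c(msg, "removedTrials: step must be 2/5/6 and trials unique")
  if (nrow(object@removedCells)) {
    key <- paste(object@removedCells$channel, object@removedCells$trial)
    if (!okStep(object@removedCells$step) || anyDuplicated(key))
      msg <- c(msg, "removedCells: step must be 2/5/6 and cells unique")
  }
  if (length(msg)) msg else TRUE
})

#' Linear ICA decomposition
#'
#' Result of blind source separation on epoched data: an unmixing matrix
#' (components x channels) and its (pseudo-)inverse mixing matrix
#' (channels x components). For a complete decomposition
#' \code{unmixing \%*\% mixing} is the identity within 1e-6. Components are
#' ordered by explained variance, descending.
#'
#' @slot mixing channels x components matrix.
#' @slot unmixing components x channels matrix.
#' @slot seed integer seed used by the estimation algorithm.
#' @slot algorithm descriptor of the estimation algorithm.
#' @slot channelLabels channels the decomposition was fitted on.
#' @slot varExplained proportion of variance per component.
#'
#' @seealso [fitIca()], [classifyComponents()], [removeComponents()]
#' @export
setClass("ICADecomposition",
  representation(
    mixing = "matrix",
    unmixing = "matrix",
    seed = "integer",
    algorithm = "character",
    channelLabels = "character",
    varExplained = "numeric"
  )
)

setValidity("ICADecomposition", function(object) {
  msg <- character()
  if (nrow(object@unmixing) != ncol(object@mixing) ||
      ncol(object@unmixing) != nrow(object@mixing))
    msg <- c(msg, "unmixing must be components x channels, mixing its transpose shape")
  p <- object@unmixing %*% object@mixing
  if (max(abs(p - diag(nrow(p)))) > 1e-6)
    msg <- c(msg, "unmixing %*% mixing must be the identity within 1e-6")
  if (length(msg)) msg else TRUE
})

#' Per-step archive of a pipeline run
#'
#' Ordered record of the intermediate dataset written after each completed
#' pipeline step, under the standardized naming convention
#' \code{<dataset_id>_<task>_<visit>_step<NN>_<stepname>.rds}, together with
#' the parameters used and an md5 checksum of the artifact.
#'
#' @slot records data.frame(step, name, path, checksum), step strictly
#'   increasing.
#' @slot parameters list of per-step parameter records, named "step<NN>".
#' @slot dir directory the artifacts were written to.
#'
#' @seealso [runPipeline()], [replayStep()]
#' @export
setClass("StepArchive",
  representation(
    records = "data.frame",
    parameters = "list",
    dir = "character"
  )
)

setValidity("StepArchive", function(object) {
  msg <- character()
  if (nrow(object@records)) {
    if (is.unsorted(object@records$step, strictly = TRUE))
      msg <- c(msg, "archive step numbers must be strictly increasing")
    if (!all(object@records$step %in% 1:7))
      msg <- c(msg, "archive steps must lie in 1..7")
  }
  if (length(msg)) msg else TRUE
})

#' Multidimensional statistic map
#'
#' Voxel-wise test statistics (t) over an n-dimensional grid such as
#' time x frequency x sensor, with the degrees of freedom needed to convert
#' statistics to p-values and the tail convention for activity detection.
#'
#' @slot values numeric array of statistics; all finite.
#' @slot dimNames names of the dimensions, e.g. c("time", "frequency").
#' @slot dimCoordinates list of axis coordinate vectors, one per dimension.
#' @slot df degrees of freedom of the statistic.
#' @slot tail "two", "pos" or "neg".
#'
#' @seealso [statMap()], [findClusters()], [permutationTest()], [uceTest()]
#' @export
setClass("StatMap",
  representation(
    values = "array",
    dimNames = "character",
    dimCoordinates = "list",
    df = "numeric",
    tail = "character"
  )
)

setValidity("StatMap", function(object) {
  msg <- character()
  if (!all(is.finite(object@values)))
    msg <- c(msg, "statistic values must be finite")
  if (length(dim(object@values)) != length(object@dimNames))
    msg <- c(msg, "dimNames length must equal array rank")
  if (!object@tail %in% c("two", "pos", "neg"))
    msg <- c(msg, "tail must be one of two/pos/neg")
  if (length(msg)) msg else TRUE
})

#' Voxel adjacency relation
#'
#' Symmetric, irreflexive neighbor relation over the voxels of a statistic
#' grid, stored as a list of neighbor index vectors (1-based, column-major
#' voxel order). Grid dimensions use orthogonal or diagonal-inclusive
#' connectivity; a declared spatial dimension uses distance-threshold
#' neighborhoods computed from sensor positions.
#'
#' @slot neighbors list of integer vectors; \code{neighbors[[v]]} are the
#'   voxels adjacent to voxel \code{v}.
#' @slot shape integer grid dimensions.
#' @slot descriptor construction descriptor.
#'
#' @seealso [buildAdjacency()], [findClusters()]
#' @export
setClass("Adjacency",
  representation(
    neighbors = "list",
    shape = "integer",
    descriptor = "character"
  )
)

setValidity("Adjacency", function(object) {
  n <- prod(object@shape)
  if (length(object@neighbors) != n)
    return("neighbors list length must equal number of voxels")
  for (v in seq_len(n)) {
    nb <- object@neighbors[[v]]
    if (any(nb == v)) return("adjacency must be irreflexive")
    if (any(nb < 1 | nb > n)) return("neighbor index out of range")
  }
  TRUE
})
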