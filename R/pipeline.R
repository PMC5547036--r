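stepNames <- c("epoch", "reject", "filter", "ica", "components",
               "finalreview", "interpolate")

#' Default configuration of the 7-step cleaning pipeline
#'
#' Returns the full parameter set of [runPipeline()] with defaults:
#' amplitude threshold 150 microvolts peak-to-peak, channel-variance
#' multiplier 5 x median, flagged-cell fraction 0.5, band-pass 1-40 Hz,
#' complete ICA with a mandatory seed, component removal driven by
#' [classifyComponents()] in auto mode, interpolation on, final average
#' reference. Override any element via the \code{config} argument of
#' [runPipeline()].
#'
#' @return named list of parameters.
#' @export
defaultPipelineConfig <- function() {
  list(window = c(-0.2, 0.8), codes = NULL,
       auto = FALSE,
       rejections = NULL,
       ampThreshold = 150, varMultiplier = 5, flaggedFraction = 0.5,
       band = c(1, 40), notch = NULL,
       nComponents = "auto", icaSeed = 1L,
       componentIndices = NULL, componentLabels = NULL,
       classThreshold = 0.5, frontalLabels = NULL,
       finalRejections = NULL,
       interpolate = TRUE, reference = "average")
}

# Average (or single-channel) reference applied to epoched data.
rereferenceEpochs <- function(ep, scheme = "average") {
  d <- ep@data
  for (i in seq_len(dim(d)[1])) {
    x <- matrix(d[i, , ], dim(d)[2], dim(d)[3])
    ref <- if (identical(scheme, "average")) colMeans(x)
           else x[match(scheme, ep@channelLabels), ]
    d[i, , ] <- sweep(x, 2, ref, "-")
  }
  ep@data <- d
  ep@reference <- if (identical(scheme, "average")) "average"
                  else paste(scheme, collapse = "-")
  ep
}

# Execute one pipeline step on the running state
# (list(rec, epochs, log, ica)). Deterministic given state + cfg.
runPipelineStep <- function(state, step, cfg) {
  if (step == 1) {
    ep <- epochRecording(state$rec, cfg$window, cfg$codes)
    state$epochs <- ep
    state$log <- newCleaningLog(ep)
  } else if (step == 2) {
    rem <- if (isTRUE(cfg$auto))
      detectGrossArtifacts(state$epochs, cfg$ampThreshold, cfg$varMultiplier,
                           cfg$flaggedFraction)
    else cfg$rejections
    if (!is.null(rem)) {
      r <- applyRejections(state$epochs, state$log, rem, step = 2)
      state$epochs <- r$epochs; state$log <- r$log
    }
  } else if (step == 3) {
    if (!is.null(cfg$band)) {
      state$epochs <- filterEpochs(state$epochs, cfg$band, cfg$notch)
      state$log@filterParams <- state$epochs@meta$filterParams
    }
  } else if (step == 4) {
    state$ica <- fitIca(state$epochs, cfg$nComponents, cfg$icaSeed)
    state$log@icaSeed <- as.integer(cfg$icaSeed)
  } else if (step == 5) {
    idx <- cfg$componentIndices
    labs <- cfg$componentLabels
    if (isTRUE(cfg$auto)) {
      cls <- classifyComponents(state$ica, state$epochs,
                                frontalLabels = cfg$frontalLabels,
                                classThreshold = cfg$classThreshold)
      idx <- cls$component[cls$label != "other"]
      labs <- cls$label[cls$label != "other"]
    }
    if (length(idx)) {
      r <- removeComponents(state$epochs, state$ica, idx, state$log, labs)
      state$epochs <- r$epochs; state$log <- r$log
    }
  } else if (step == 6) {
    rem <- if (isTRUE(cfg$auto))
      detectGrossArtifacts(state$epochs, cfg$ampThreshold, cfg$varMultiplier,
                           cfg$flaggedFraction)
    else cfg$finalRejections
    if (!is.null(rem)) {
      r <- applyRejections(state$epochs, state$log, rem, step = 6)
      state$epochs <- r$epochs; state$log <- r$log
    }
  } else if (step == 7) {
    if (isTRUE(cfg$interpolate) && nrow(state$epochs@channelPositions) > 0)
      state$epochs <- interpolateChannels(state$epochs, state$log)
    state$epochs <- rereferenceEpochs(state$epochs, cfg$reference)
  }
  state
}

archiveName <- function(rec, step) {
  meta <- rec@meta
  sprintf("%s_%s_%s_step%02d_%s.rds",
          rec@id, meta$task %||% "task", meta$visit %||% "01",
          step, stepNames[step])
}

#' Run the 7-step cleaning pipeline with per-step archiving
#'
#' Executes the cleaning workflow in fixed order: (1) epoch, (2) gross
#' artifact rejection, (3) filtering, (4) ICA fit, (5) component removal,
#' (6) final review, (7) interpolation + re-referencing. Large random and
#' high-amplitude artifacts are handled before the ICA fit so the
#' decomposition is not dominated by them. After each step the full
#' intermediate state and the step parameters are written to a
#' [StepArchive-class] under the standardized naming convention
#' \code{<dataset_id>_<task>_<visit>_step<NN>_<stepname>.rds} with an md5
#' checksum. In \code{auto} mode Steps 2/6 take their removals from
#' [detectGrossArtifacts()] and Step 5 from [classifyComponents()];
#' otherwise removals come from the declarative lists in \code{config}.
#'
#' On failure the archive retains all completed steps and the error names
#' the failed step.
#'
#' @param rec a harmonized [EEGRecording-class].
#' @param config named list overriding [defaultPipelineConfig()].
#' @param outDir archive directory (created; default a fresh temporary
#'   directory).
#' @return list(epochs, log, archive).
#' @export
runPipeline <- function(rec, config = list(), outDir = tempfile("archive")) {
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  archive <- new("StepArchive",
                 records = data.frame(step = integer(), name = character(),
                                      path = character(),
                                      checksum = character(),
                                      stringsAsFactors = FALSE),
                 parameters = list(), dir = outDir)
  state <- list(rec = rec, epochs = NULL, log = NULL, ica = NULL)
  for (step in 1:7) {
    state <- tryCatch(
      runPipelineStep(state, step, cfg),
      error = function(e)
        stop(sprintf("pipeline failed at step %d (%s): %s [archive: %s]",
                     step, stepNames[step], conditionMessage(e), outDir),
             call. = FALSE))
    nm <- archiveName(rec, step)
    path <- file.path(outDir, nm)
    saveRDS(list(epochs = state$epochs, log = state$log, ica = state$ica),
            path)
    archive@records <- rbind(archive@records,
                             data.frame(step = step, name = nm, path = path,
                                        checksum = md5OfFile(path),
                                        stringsAsFactors = FALSE))
    archive@parameters[[sprintf("step%02d", step)]] <- cfg
  }
  list(epochs = state$epochs, log = state$log, archive = archive)
}

#' Re-run an archived pipeline step from its predecessor
#'
#' Loads the archived state of step \code{step - 1} (or takes \code{rec}
#' for step 1), re-executes the step with its archived parameters, and
#' returns the recomputed state; comparing it with the archived successor
#' verifies archive replayability.
#'
#' @param archive a [StepArchive-class] from [runPipeline()].
#' @param step step number 1-7.
#' @param rec the original recording (required to replay step 1).
#' @return list(epochs, log, ica).
#' @export
replayStep <- function(archive, step, rec = NULL) {
  cfg <- archive@parameters[[sprintf("step%02d", step)]]
  if (is.null(cfg)) stop("step ", step, " is not in the archive")
  if (step == 1) {
    if (is.null(rec)) stop("replaying step 1 requires the original recording")
    state <- list(rec = rec, epochs = NULL, log = NULL, ica = NULL)
  } else {
    prev <- archive@records$path[archive@records$step == step - 1]
    state <- c(list(rec = rec), readRDS(prev))
  }
  state <- runPipelineStep(state, step, cfg)
  state[c("epochs", "log", "ica")]
}

#' Write cleaning summary matrices as TSV
#'
#' @param summary output of [summarizeCleaning()].
#' @param dir output directory.
#' @return paths of the two TSV files, invisibly.
#' @export
writeCleaningSummary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "trials_removed_per_channel.tsv")
  p2 <- file.path(dir, "components_removed_per_dataset.tsv")
  utils::write.table(summary$trialsPerChannel, p1, sep = "\t",
                     col.names = NA, quote = FALSE)
  utils::write.table(summary$componentsPerDataset, p2, sep = "\t",
                     col.names = NA, quote = FALSE)
  invisible(c(p1, p2))
}
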