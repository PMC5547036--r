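test_that("epoching yields one full-length trial per interior event", {
  g <- quickSynth(seed = 1, duration = 20, nEvents = 10)
  ep <- epochRecording(g$recording, c(-0.2, 0.8), codes = 1)
  expect_equal(nTrials(ep), 10)
  expect_equal(nSamples(ep), samplingRate(g$recording) * 1.0)
  expect_equal(diff(range(timeAxis(ep))) + 1 / samplingRate(ep), 1.0,
               tolerance = 1e-9)
})

test_that("events too close to the recording edge are dropped and reported", {
  rec <- newRecording("e", matrix(rnorm(300), 1), 100, "A",
                      events = makeEvents(c(5, 150), 1))
  ep <- epochRecording(rec, c(-0.2, 0.8))
  expect_equal(nTrials(ep), 1)
  expect_equal(recordingMeta(ep)$dropped_events, 1L)
  expect_error(epochRecording(rec, c(-0.2, 0.8), codes = 99),
               "empty-epochs")
})

test_that("the averaged epoch peaks at the injected latency", {
  g <- quickSynth(seed = 2, duration = 20, nEvents = 10, noise = 0,
                  oscillations = list())
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  avg <- averageErp(ep)
  best <- which.max(abs(avg[which.max(g$config$erp$topography), ]))
  expect_lte(abs(timeAxis(ep)[best] - g$config$erp$latency),
             1 / samplingRate(ep))
})

test_that("gross-artifact detection flags planted outliers and nothing else", {
  g <- quickSynth(seed = 3, duration = 20, nEvents = 10, noise = 3)
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  expect_equal(nrow(detectGrossArtifacts(ep, 150)$cells), 0)

  ep2 <- ep
  ep2@data[4, 7, 100:120] <- ep2@data[4, 7, 100:120] + 500
  sug <- detectGrossArtifacts(ep2, 150)
  expect_equal(sug$cells,
               data.frame(channel = channelLabels(ep)[7], trial = 4L,
                          stringsAsFactors = FALSE))
  expect_length(sug$channels, 0)

  ep3 <- ep
  ep3@data[, 5, ] <- 7.5                     # flat channel, variance 0
  sug3 <- detectGrossArtifacts(ep3, 150)
  expect_true(channelLabels(ep)[5] %in% sug3$channels)
  flatVar <- var(as.vector(ep3@data[, 5, ]))
  expect_identical(flatVar, 0)               # oracle: direct variance
})

test_that("rejections update data and log consistently and reject double removal", {
  g <- quickSynth(seed = 4, duration = 20, nEvents = 10)
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  log <- newCleaningLog(ep)

  r0 <- applyRejections(ep, log, list(), step = 2)
  expect_identical(signalData(r0$epochs), signalData(ep))

  r1 <- applyRejections(ep, log, list(trials = 3L), step = 2)
  expect_equal(nTrials(r1$epochs), 9)
  expect_equal(r1$log@removedTrials,
               data.frame(trial = 3L, step = 2L))
  expect_error(applyRejections(r1$epochs, r1$log, list(trials = 3L), 6),
               "consistency error")

  r2 <- applyRejections(r1$epochs, r1$log,
                        list(channels = "Fz",
                             cells = data.frame(channel = "Cz", trial = 5L)),
                        step = 6)
  expect_equal(nChannels(r2$epochs), 18)
  expect_false(r2$epochs@cellMask[match(5L, r2$epochs@trialIndices),
                                  match("Cz", channelLabels(r2$epochs))])
})

test_that("a saved log replays to an identical surviving-data mask", {
  g <- quickSynth(seed = 5, duration = 20, nEvents = 10)
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  st <- applyRejections(ep, newCleaningLog(ep),
                        list(trials = c(2L, 9L), channels = "O1",
                             cells = data.frame(channel = c("Fz", "P3"),
                                                trial = c(4L, 6L))),
                        step = 2)
  st <- applyRejections(st$epochs, st$log, list(trials = 7L), step = 6)
  replayed <- replayLog(ep, st$log)
  expect_identical(currentMask(replayed$epochs, replayed$log),
                   currentMask(st$epochs, st$log))
  expect_identical(survivingMask(st$log), currentMask(st$epochs, st$log))
  # oracle: set arithmetic on indices
  m <- matrix(TRUE, 10, 19, dimnames = list(1:10, channelLabels(ep)))
  m[c(2, 9, 7), ] <- FALSE
  m[, "O1"] <- FALSE
  m[4, "Fz"] <- FALSE; m[6, "P3"] <- FALSE
  expect_identical(survivingMask(st$log), m)
})

test_that("filtering honors pass band, notch and stop band", {
  rate <- 500
  tt <- (0:(rate - 1)) / rate
  mkEp <- function(wave) {
    d <- array(0, c(4, 2, rate))
    for (i in 1:4) for (c in 1:2) d[i, c, ] <- wave
    new("EEGEpochs", data = d, timeAxis = tt, trialCodes = rep(1L, 4),
        trialIndices = 1:4, channelLabels = c("A", "B"),
        channelPositions = matrix(numeric(), 0, 3,
                                  dimnames = list(NULL, c("x", "y", "z"))),
        samplingRate = rate, reference = "unknown",
        cellMask = matrix(TRUE, 4, 2), meta = list())
  }
  sin10 <- sin(2 * pi * 10 * tt)
  f1 <- filterEpochs(mkEp(sin10), c(1, 40))
  mid <- 100:400
  expect_lt(abs(max(abs(f1@data[1, 1, mid])) - 1), 0.05)

  sin60 <- sin(2 * pi * 60 * tt)
  f2 <- filterEpochs(mkEp(sin60), c(1, 100), notch = 60)
  expect_lt(rms(f2@data[1, 1, mid]), 0.1 * rms(sin60[mid]))

  set.seed(6)
  fn <- filterEpochs(mkEp(rnorm(rate)), c(1, 40))
  p <- Mod(fft(fn@data[1, 1, ]))^2
  freqs <- (0:(rate - 1))
  passP <- mean(p[freqs >= 5 & freqs <= 35])
  stopP <- mean(p[freqs >= 50 & freqs <= 250])
  expect_gt(10 * log10(passP / stopP), 20)
  expect_error(filterEpochs(mkEp(sin10), c(40, 1)), "configuration error")
})

test_that("ICA recovers a known mixture and obeys its linear contract", {
  set.seed(7)
  n <- 4000
  S <- rbind(sin(2 * pi * 3 * (1:n) / 500),
             sign(sin(2 * pi * 7.3 * (1:n) / 500)),
             runif(n, -1, 1))
  A <- matrix(c(1, 0.5, -0.3, 0.2, 1, 0.4, -0.6, 0.3, 1), 3, 3)
  X <- A %*% S
  d <- array(0, c(8, 3, n / 8))
  for (i in 1:8) d[i, , ] <- X[, ((i - 1) * n / 8 + 1):(i * n / 8)]
  ep <- new("EEGEpochs", data = d, timeAxis = (0:(n / 8 - 1)) / 500,
            trialCodes = rep(1L, 8), trialIndices = 1:8,
            channelLabels = c("A", "B", "C"),
            channelPositions = matrix(numeric(), 0, 3,
                                      dimnames = list(NULL, c("x", "y", "z"))),
            samplingRate = 500, reference = "unknown",
            cellMask = matrix(TRUE, 8, 3), meta = list())
  ica <- fitIca(ep, seed = 10)
  ica2 <- fitIca(ep, seed = 10)
  expect_identical(ica@unmixing, ica2@unmixing)

  rec <- ica@unmixing %*% X
  for (k in 1:3)
    expect_gt(max(abs(cor(t(rec))[k, ])[abs(cor(rec[k, ], t(S))) ==
                                          max(abs(cor(rec[k, ], t(S))))] * 0 +
                    max(abs(cor(rec[k, ], t(S))))), 0.95)

  expect_lt(max(abs(ica@unmixing %*% ica@mixing - diag(3))), 1e-6)

  r0 <- removeComponents(ep, ica, integer(), newCleaningLog(ep))
  expect_lt(max(abs(signalData(r0$epochs) - signalData(ep))), 1e-6)
  rAll <- removeComponents(ep, ica, 1:3, newCleaningLog(ep))
  expect_lt(max(abs(signalData(rAll$epochs))), 1e-6)
  expect_error(removeComponents(ep, ica, 9L, newCleaningLog(ep)),
               "index error")
})

test_that("insufficient data for ICA raises a data-length error", {
  d <- array(rnorm(2 * 5 * 30), c(2, 5, 30))
  ep <- new("EEGEpochs", data = d, timeAxis = (0:29) / 100,
            trialCodes = rep(1L, 2), trialIndices = 1:2,
            channelLabels = paste0("C", 1:5),
            channelPositions = matrix(numeric(), 0, 3,
                                      dimnames = list(NULL, c("x", "y", "z"))),
            samplingRate = 100, reference = "unknown",
            cellMask = matrix(TRUE, 2, 5), meta = list())
  expect_error(fitIca(ep, seed = 1), "data-length error")
})

test_that("planted artifact components are labelled by class", {
  g <- quickSynth(seed = 8, duration = 40, nEvents = 20, noise = 4,
                  artifacts = list(blinkRate = 15, blinkAmplitude = 150))
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  ep <- filterEpochs(ep, c(1, 45))
  ica <- fitIca(ep, seed = 11)
  cls <- classifyComponents(ica, ep)
  expect_true(all(cls$score >= 0 & cls$score <= 1))
  expect_true("blink" %in% cls$label)
  # oracle: the blink-labelled component correlates best with a frontal
  # low-frequency signature
  S <- mseeg:::componentSources(ica, ep)
  blinkIdx <- cls$component[cls$label == "blink"][1]
  frontal <- which(channelLabels(ep) %in% c("Fp1", "Fp2"))
  X <- t(apply(signalData(ep), 2, function(m) as.vector(t(m))))
  frontSig <- colMeans(X[frontal, , drop = FALSE])
  cors <- abs(apply(S, 1, cor, y = frontSig))
  expect_equal(blinkIdx, which.max(cors))
})

test_that("a flat-topography flat-spectrum component is labelled other", {
  # hand-built decomposition whose first component has a uniform
  # topography and a white time course
  set.seed(12)
  A <- cbind(rep(0.5, 4), c(1, -1, 0, 0) / sqrt(2),
             c(0, 0, 1, -1) / sqrt(2), c(1, 1, -1, -1) / 2)
  S <- matrix(rnorm(4 * 1500), 4)
  X <- A %*% S
  d <- array(0, c(6, 4, 250))
  for (i in 1:6) d[i, , ] <- X[, ((i - 1) * 250 + 1):(i * 250)]
  ep <- new("EEGEpochs", data = d, timeAxis = (0:249) / 250,
            trialCodes = rep(1L, 6), trialIndices = 1:6,
            channelLabels = c("Fp1", "Fp2", "Cz", "Pz"),
            channelPositions = as.matrix(
              data.frame(x = c(-0.3, 0.3, 0, 0), y = c(0.9, 0.9, 0, -0.7),
                         z = c(0.3, 0.3, 1, 0.7),
                         row.names = c("Fp1", "Fp2", "Cz", "Pz"))),
            samplingRate = 250, reference = "unknown",
            cellMask = matrix(TRUE, 6, 4), meta = list())
  ica <- new("ICADecomposition", mixing = A, unmixing = solve(A),
             seed = 1L, algorithm = "hand-built",
             channelLabels = channelLabels(ep),
             varExplained = rep(0.25, 4))
  cls <- classifyComponents(ica, ep)
  expect_equal(cls$label[1], "other")
})

test_that("removing the blink component moves the average toward ground truth", {
  g <- quickSynth(seed = 14, duration = 40, nEvents = 20, noise = 3,
                  artifacts = list(blinkRate = 20, blinkAmplitude = 150))
  clean <- genRecording(synthConfig(duration = 40, nEvents = 20, noise = 3,
                                    seed = 14))
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  epClean <- epochRecording(clean$recording, c(-0.2, 0.8))
  ica <- fitIca(ep, seed = 15)
  cls <- classifyComponents(ica, ep)
  idx <- cls$component[cls$label == "blink"]
  expect_gt(length(idx), 0)
  res <- removeComponents(ep, ica, idx, newCleaningLog(ep))
  before <- rms(averageErp(ep), averageErp(epClean))
  after <- rms(averageErp(res$epochs), averageErp(epClean))
  expect_lt(after, before)
})

test_that("spherical-spline interpolation is self-consistent and conservative", {
  g <- quickSynth(seed = 16, duration = 20, nEvents = 10, noise = 4)
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  log <- newCleaningLog(ep)

  expect_identical(interpolateChannels(ep, log), ep)   # nothing removed

  # make channel Pz the spline prediction of the others, then remove it
  pos <- ep@channelPositions
  others <- setdiff(channelLabels(ep), "Pz")
  M <- sphericalSplineMatrix(pos[others, ], pos["Pz", , drop = FALSE])
  target <- match("Pz", channelLabels(ep))
  for (i in seq_len(nTrials(ep)))
    ep@data[i, target, ] <- M %*% matrix(ep@data[i, -target, ],
                                         length(others))
  truth <- ep@data[, target, ]
  st <- applyRejections(ep, log, list(channels = "Pz"), step = 2)
  out <- interpolateChannels(st$epochs, st$log)
  expect_equal(nChannels(out), 19)
  expect_equal(channelLabels(out), channelLabels(ep))
  recovered <- out@data[, match("Pz", channelLabels(out)), ]
  expect_lt(rms(recovered, truth) / rms(truth), 0.01)

  tooFew <- applyRejections(ep, newCleaningLog(ep),
                            list(channels = channelLabels(ep)[1:16]),
                            step = 2)
  expect_error(interpolateChannels(tooFew$epochs, tooFew$log),
               "interpolation error")
})

test_that("a pass-through pipeline run is a near-identity with 7 archived steps", {
  g <- quickSynth(seed = 17, duration = 20, nEvents = 10)
  res <- runPipeline(g$recording,
                     list(band = NULL, interpolate = FALSE,
                          reference = "average", icaSeed = 3))
  expect_equal(res$archive@records$step, 1:7)
  expect_true(all(diff(res$archive@records$step) > 0))
  ep0 <- epochRecording(g$recording, c(-0.2, 0.8))
  ref0 <- mseeg:::rereferenceEpochs(ep0, "average")
  expect_lt(max(abs(signalData(res$epochs) - signalData(ref0))), 1e-6)
})

test_that("pipeline provenance and archives replay exactly", {
  g <- quickSynth(seed = 18, duration = 30, nEvents = 15, noise = 5,
                  artifacts = list(blinkRate = 10, emgRate = 5,
                                   flatChannel = "T5"))
  res <- runPipeline(g$recording, list(auto = TRUE, icaSeed = 4))
  expect_identical(survivingMask(res$log),
                   currentMask(res$epochs, res$log))
  for (step in 2:7) {
    redo <- replayStep(res$archive, step)
    stored <- readRDS(res$archive@records$path[step])
    expect_lt(max(abs(signalData(redo$epochs) -
                        signalData(stored$epochs))), 1e-6)
    expect_identical(survivingMask(redo$log), survivingMask(stored$log))
  }
  redo1 <- replayStep(res$archive, 1, rec = g$recording)
  stored1 <- readRDS(res$archive@records$path[1])
  expect_identical(signalData(redo1$epochs), signalData(stored1$epochs))
  # step tags never precede their step order
  expect_true(all(res$log@removedComponents$component > 0))
  steps <- c(res$log@removedChannels$step, res$log@removedTrials$step,
             res$log@removedCells$step)
  expect_true(all(steps %in% c(2L, 5L, 6L)))
})

test_that("trial/channel counts are conserved through removals", {
  g <- quickSynth(seed = 19, duration = 20, nEvents = 10)
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  st <- applyRejections(ep, newCleaningLog(ep),
                        list(trials = c(1L, 4L), channels = c("Fz", "O2")),
                        step = 2)
  expect_equal(nTrials(st$epochs) + nrow(st$log@removedTrials), 10)
  expect_equal(nChannels(st$epochs) + nrow(st$log@removedChannels), 19)
})

test_that("cleaning summaries aggregate logs correctly", {
  g <- quickSynth(seed = 20, duration = 20, nEvents = 10)
  ep <- epochRecording(g$recording, c(-0.2, 0.8))
  mkLog <- function(cells = NULL, comps = NULL) {
    log <- newCleaningLog(ep)
    if (!is.null(cells))
      log <- applyRejections(ep, log, list(cells = cells), step = 2)$log
    if (!is.null(comps))
      log@removedComponents <- comps
    log
  }
  expect_error(summarizeCleaning(list(), character()), "empty-summary")

  lEmpty <- mkLog()
  s0 <- summarizeCleaning(list(lEmpty, lEmpty), c("ctl", "ctl"))
  expect_true(all(s0$trialsPerChannel == 0))
  expect_true(all(s0$componentsPerDataset == 0))

  lFz <- mkLog(cells = data.frame(channel = rep("Fz", 3), trial = 1:3))
  s1 <- summarizeCleaning(list(lFz, lEmpty), c("ctl", "ctl"))
  expect_equal(s1$trialsPerChannel["Fz", "ctl"], 1.5)

  set.seed(21)
  lComp <- mkLog(comps = data.frame(component = 1:3,
                                    label = c("blink", "EMG", "blink"),
                                    stringsAsFactors = FALSE))
  s2 <- summarizeCleaning(list(lComp), "mdd")
  expect_equal(s2$componentsPerDataset["blink", 1], 2)
  expect_equal(s2$componentsPerDataset["EMG", 1], 1)

  # recount oracle on random logs
  for (k in 1:5) {
    trs <- sample(1:10, sample(0:3, 1))
    lg <- newCleaningLog(ep)
    if (length(trs))
      lg <- applyRejections(ep, lg, list(trials = trs), step = 2)$log
    s <- summarizeCleaning(list(lg), "g")
    expect_true(all(s$trialsPerChannel[, 1] == length(trs)))
  }
})
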