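#' Fit an ICA decomposition on epoched data (Step 4)
#'
#' Estimates an independent component decomposition of the concatenated
#' trials using symmetric FastICA with a tanh contrast on PCA-whitened
#' data. The estimation is deterministic for a fixed seed. The applied
#' transform is purely linear: sources = unmixing x data (uncentered), and
#' \code{unmixing \%*\% mixing} is the identity within 1e-6, so removing no
#' components reconstructs the data exactly and removing all components of
#' a complete decomposition annihilates it. Components are ordered by
#' explained variance, descending.
#'
#' @param ep an [EEGEpochs-class]; concatenated samples must be at least
#'   20 x nChannels.
#' @param nComponents number of components or \code{"auto"} (= number of
#'   channels, reduced to the numerical rank of the data).
#' @param seed mandatory integer seed.
#' @param maxIter,tol FastICA iteration controls.
#' @return an [ICADecomposition-class].
#' @export
fitIca <- function(ep, nComponents = "auto", seed, maxIter = 500,
                   tol = 1e-8) {
  seed <- as.integer(seed)
  d <- ep@data
  nch <- dim(d)[2]
  X <- t(apply(d, 2, function(m) as.vector(t(m))))   # channels x (trials*samples)
  if (is.null(dim(X))) X <- matrix(X, nrow = nch)
  N <- ncol(X)
  if (N < 20 * nch)
    stop("data-length error: need at least 20 samples per channel, have ",
         round(N / nch, 1), call. = FALSE)

  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- Xc %*% t(Xc) / N
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  k <- if (identical(nComponents, "auto")) min(nch, rank)
       else min(as.integer(nComponents), rank)
  K <- diag(1 / sqrt(eg$values[seq_len(k)]), k) %*%
    t(eg$vectors[, seq_len(k), drop = FALSE])        # k x nch whitener
  Z <- K %*% Xc

  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), k) %*% t(e$vectors) %*% W
  }
  W <- sym(W)
  for (it in seq_len(maxIter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Wn <- G %*% t(Z) / N - diag(rowMeans(1 - G^2), k) %*% W
    Wn <- sym(Wn)
    delta <- max(abs(abs(rowSums(Wn * W)) - 1))
    W <- Wn
    if (delta < tol) break
  }

  unmixing <- W %*% K                                 # k x nch
  mixing <- if (k == nch) solve(unmixing) else
    t(unmixing) %*% solve(unmixing %*% t(unmixing))   # right pseudo-inverse
  S <- unmixing %*% X
  varByComp <- vapply(seq_len(k), function(j)
    sum(mixing[, j]^2) * stats::var(S[j, ]), 0)
  ord <- order(varByComp, decreasing = TRUE)
  new("ICADecomposition",
      mixing = mixing[, ord, drop = FALSE],
      unmixing = unmixing[ord, , drop = FALSE],
      seed = seed, algorithm = "fastica-symmetric-tanh",
      channelLabels = ep@channelLabels,
      varExplained = varByComp[ord] / sum(varByComp))
}

# Component time courses on the concatenated epochs.
componentSources <- function(ica, ep) {
  X <- t(apply(ep@data, 2, function(m) as.vector(t(m))))
  if (is.null(dim(X))) X <- matrix(X, nrow = dim(ep@data)[2])
  ica@unmixing %*% X
}

#' Heuristic artifact classification of ICA components (Step 5)
#'
#' Scores each component for the artifact classes extracted during
#' cleaning, all scores in [0, 1]:
#' \itemize{
#' \item blink: frontal concentration of the topography x low-frequency
#'   (< 4 Hz) power fraction of the time course;
#' \item eye-movement: frontal left/right antisymmetry x low-frequency
#'   power fraction;
#' \item EMG: power fraction above 20 Hz;
#' \item discontinuity: single-channel concentration of the topography;
#' \item ECG: peak autocorrelation of the rectified time course at lags
#'   0.67-1.25 s (0.8-1.5 Hz periodicity).
#' }
#' The label is the argmax class where the score exceeds
#' \code{classThreshold}, else \code{"other"}.
#'
#' @param ica an [ICADecomposition-class] fitted on \code{ep}.
#' @param ep the [EEGEpochs-class] the decomposition was fitted on.
#' @param frontalLabels channel labels treated as frontal (default: labels
#'   beginning Fp/AF/F).
#' @param classThreshold minimum winning score (default 0.5).
#' @return data.frame(component, label, score) plus per-class score
#'   columns.
#' @export
classifyComponents <- function(ica, ep, frontalLabels = NULL,
                               classThreshold = 0.5) {
  labs <- ica@channelLabels
  if (is.null(frontalLabels))
    frontalLabels <- labs[grepl("^(Fp|AF|F)[0-9z]", labs)]
  frontal <- labs %in% frontalLabels
  pos <- ep@channelPositions
  S <- componentSources(ica, ep)
  rate <- ep@samplingRate
  k <- nrow(S)
  n <- ncol(S)
  freq <- (seq_len(n) - 1) / n * rate
  half <- freq <= rate / 2

  res <- lapply(seq_len(k), function(j) {
    a <- abs(ica@mixing[, j])
    aN <- a / sum(a)
    s <- S[j, ]
    P <- Mod(stats::fft(s))^2
    P <- P[half]; fr <- freq[half]
    Ptot <- sum(P[fr > 0])
    lowFrac <- sum(P[fr > 0 & fr < 4]) / Ptot
    # EMG: compare power DENSITY in the muscle band against the low band,
    # so a flat (white) spectrum scores 0 rather than its bandwidth share
    hiDens <- mean(P[fr > 20 & fr <= min(100, rate / 2)])
    loDens <- mean(P[fr > 0.5 & fr <= 10])
    hiFrac <- max(0, 2 * (hiDens / (hiDens + loDens) - 0.5))
    frontalFrac <- sum(aN[frontal])
    conc <- max(a^2) / sum(a^2)
    # lateral antisymmetry of the frontal topography (x > 0 vs x < 0)
    anti <- 0
    if (nrow(pos) && any(frontal)) {
      w <- ica@mixing[, j]
      xs <- pos[labs, "x"]
      l <- frontal & xs < 0; r <- frontal & xs > 0
      if (any(l) && any(r)) {
        num <- abs(mean(w[l]) - mean(w[r]))
        den <- max(abs(w[frontal])) * 2
        anti <- min(1, num / den)
      }
    }
    # cardiac periodicity: autocorrelation of the rectified source
    env <- abs(s) - mean(abs(s))
    lags <- round(seq(0.67, 1.25, length.out = 12) * rate)
    lags <- lags[lags < n - 1]
    ac <- vapply(lags, function(L) {
      v <- sum(env[1:(n - L)] * env[(L + 1):n]) / sum(env^2)
      max(0, v)
    }, 0)
    scores <- c(blink = frontalFrac * lowFrac,
                `eye-movement` = anti * lowFrac,
                EMG = hiFrac,
                discontinuity = conc,
                ECG = if (length(ac)) max(ac) else 0)
    win <- which.max(scores)
    lab <- if (scores[win] > classThreshold) names(scores)[win] else "other"
    c(list(component = j, label = lab, score = unname(scores[win])),
      as.list(scores))
  })
  out <- do.call(rbind, lapply(res, as.data.frame,
                               stringsAsFactors = FALSE))
  names(out) <- c("component", "label", "score", "blink", "eye_movement",
                  "EMG", "discontinuity", "ECG")
  out
}

#' Remove ICA components from epochs (Step 5)
#'
#' Reconstructs the data without the listed components:
#' \code{x' = x - mixing[, idx] (unmixing[idx, ] x)} per trial. An empty
#' index set returns the data unchanged. Removals (with labels when
#' supplied) and the ICA seed are recorded in the log.
#'
#' @param ep an [EEGEpochs-class].
#' @param ica the fitted [ICADecomposition-class].
#' @param indices component indices to remove (may be empty).
#' @param log the dataset's [CleaningLog-class].
#' @param labels optional artifact label per removed component.
#' @return list(epochs, log).
#' @export
removeComponents <- function(ep, ica, indices, log, labels = NULL) {
  indices <- as.integer(indices)
  k <- ncol(ica@mixing)
  if (length(indices) && (any(indices < 1) || any(indices > k)))
    stop("index error: component indices must lie in 1..", k, call. = FALSE)
  if (length(indices)) {
    P <- ica@mixing[, indices, drop = FALSE] %*%
      ica@unmixing[indices, , drop = FALSE]
    d <- ep@data
    for (i in seq_len(dim(d)[1])) {
      x <- matrix(d[i, , ], dim(d)[2], dim(d)[3])
      d[i, , ] <- x - P %*% x
    }
    ep@data <- d
  }
  if (is.null(labels)) labels <- rep("other", length(indices))
  log@icaSeed <- ica@seed
  if (length(indices))
    log@removedComponents <- rbind(
      log@removedComponents,
      data.frame(component = indices, label = labels,
                 stringsAsFactors = FALSE))
  list(epochs = ep, log = log)
}
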