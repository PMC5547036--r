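# Legendre polynomials P_1..P_n evaluated at x (vector): returns n x length(x).
legendreUpTo <- function(n, x) {
  out <- matrix(0, n, length(x))
  pPrev <- rep(1, length(x))        # P_0
  p <- x                            # P_1
  out[1, ] <- p
  if (n >= 2) for (k in 2:n) {
    pNext <- ((2 * k - 1) * x * p - (k - 1) * pPrev) / k
    out[k, ] <- pNext
    pPrev <- p; p <- pNext
  }
  out
}

# Spherical-spline g function (order m, nTerms Legendre terms) at cosine
# angles x.
splineG <- function(x, m = 4, nTerms = 50) {
  n <- seq_len(nTerms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendreUpTo(nTerms, x)
  as.vector(coef %*% P) / (4 * pi)
}

#' Spherical-spline prediction matrix
#'
#' Linear operator predicting signals at target electrode positions from
#' signals at source positions via spherical-spline interpolation
#' (order-4 splines, 50 Legendre terms, light Tikhonov regularization).
#'
#' @param goodPos source positions (rows, unit sphere).
#' @param badPos target positions.
#' @param m spline order.
#' @param lambda regularization added to the spline kernel diagonal.
#' @return matrix nrow(badPos) x nrow(goodPos).
#' @export
sphericalSplineMatrix <- function(goodPos, badPos, m = 4, lambda = 1e-5) {
  norm1 <- function(p) p / sqrt(rowSums(p^2))
  g <- norm1(as.matrix(goodPos)); b <- norm1(as.matrix(badPos))
  ng <- nrow(g)
  cosGG <- pmin(1, pmax(-1, g %*% t(g)))
  cosBG <- pmin(1, pmax(-1, b %*% t(g)))
  Ggg <- matrix(splineG(as.vector(cosGG), m), ng, ng) + diag(lambda, ng)
  Gbg <- matrix(splineG(as.vector(cosBG), m), nrow(b), ng)
  A <- rbind(cbind(Ggg, 1), c(rep(1, ng), 0))
  Ainv <- solve(A)
  cbind(Gbg, 1) %*% Ainv[, seq_len(ng), drop = FALSE]
}

#' Reinstate removed channels by spherical-spline interpolation (Step 7)
#'
#' Interpolates every channel recorded as removed in the log from the
#' surviving channels, using spherical splines on the electrode positions,
#' and restores the original channel order. Requires positions for all
#' channels and at least 4 surviving channels.
#'
#' @param ep an [EEGEpochs-class] (after Steps 1-6).
#' @param log the dataset's [CleaningLog-class].
#' @return an [EEGEpochs-class] with the full original channel set.
#' @export
interpolateChannels <- function(ep, log) {
  bad <- log@removedChannels$label
  if (!length(bad)) return(ep)
  good <- ep@channelLabels
  if (length(good) < 4)
    stop("interpolation error: need at least 4 surviving channels",
         call. = FALSE)
  pos <- ep@channelPositions
  missingPos <- setdiff(c(good, bad), rownames(pos))
  if (length(missingPos))
    stop("interpolation error: no positions for channel(s): ",
         paste(missingPos, collapse = ", "), call. = FALSE)
  M <- sphericalSplineMatrix(pos[good, , drop = FALSE],
                             pos[bad, , drop = FALSE])
  nt <- dim(ep@data)[1]; ns <- dim(ep@data)[3]
  order0 <- log@channels[log@channels %in% c(good, bad)]
  newData <- array(0, c(nt, length(order0), ns))
  newMask <- matrix(TRUE, nt, length(order0))
  for (i in seq_len(nt)) {
    xg <- matrix(ep@data[i, , ], length(good), ns)
    xb <- M %*% xg
    newData[i, match(good, order0), ] <- xg
    newData[i, match(bad, order0), ] <- xb
  }
  newMask[, match(good, order0)] <- ep@cellMask
  ep@data <- newData
  ep@cellMask <- newMask
  ep@channelLabels <- order0
  ep@meta$interpolated <- bad
  ep
}
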