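#' @importFrom stats rnorm median sd var fft approx
NULL

emptyEvents <- function() {
  data.frame(onset_sample = integer(), code = integer(),
             label = character(), stringsAsFactors = FALSE)
}

#' Build an event matrix
#'
#' @param onsets 0-based integer sample indices, nondecreasing.
#' @param codes integer event codes (recycled).
#' @param labels event labels (default: code as character).
#' @return data.frame(onset_sample, code, label)
#' @export
makeEvents <- function(onsets, codes = 1L, labels = NULL) {
  onsets <- as.integer(round(onsets))
  codes <- rep_len(as.integer(codes), length(onsets))
  if (is.null(labels)) labels <- as.character(codes)
  labels <- rep_len(as.character(labels), length(onsets))
  ord <- order(onsets)
  data.frame(onset_sample = onsets[ord], code = codes[ord],
             label = labels[ord], stringsAsFactors = FALSE)
}

#' Construct an EEGRecording
#'
#' @param id recording identifier.
#' @param data channels x samples numeric matrix, microvolts.
#' @param samplingRate Hz.
#' @param channelLabels one label per row of \code{data}.
#' @param channelPositions optional matrix/data.frame with columns x, y, z
#'   and rownames (or a \code{label} column) naming electrodes.
#' @param reference reference descriptor.
#' @param events event matrix as from [makeEvents()].
#' @param meta named list of acquisition annotations.
#' @return an [EEGRecording-class] object.
#' @export
newRecording <- function(id, data, samplingRate, channelLabels,
                         channelPositions = NULL, reference = "unknown",
                         events = emptyEvents(), meta = list()) {
  data <- as.matrix(data)
  if (is.null(channelPositions)) {
    channelPositions <- matrix(numeric(), 0, 3,
                               dimnames = list(NULL, c("x", "y", "z")))
  } else {
    channelPositions <- as.positions(channelPositions)
  }
  new("EEGRecording", id = as.character(id), samplingRate = samplingRate,
      data = data, channelLabels = as.character(channelLabels),
      channelPositions = channelPositions, reference = reference,
      events = events, meta = meta)
}

# Coerce a montage table (label,x,y,z or rownames + x,y,z) to a positions
# matrix with label rownames.
as.positions <- function(m) {
  if (is.data.frame(m) && "label" %in% names(m)) {
    lab <- as.character(m$label)
    m <- as.matrix(m[, c("x", "y", "z")])
    rownames(m) <- lab
  } else {
    m <- as.matrix(m)
    colnames(m) <- c("x", "y", "z")
  }
  storage.mode(m) <- "double"
  m
}

#' Nominal 10-20 montage (19 electrodes)
#'
#' Nominal unit-sphere positions for the 19 standard 10-20 electrodes
#' (nose along +y, left along -x, vertex +z). Angles are the conventional
#' equidistant placements; adequate for electrode matching, topography
#' weighting and spherical-spline interpolation on synthetic data.
#'
#' @return data.frame(label, x, y, z)
#' @export
montage1020 <- function() {
  # (label, inclination from vertex in deg, azimuth in deg from +x toward +y)
  tab <- rbind(
    c("Cz", 0, 0),
    c("Fz", 45, 90), c("Pz", 45, -90), c("C3", 45, 180), c("C4", 45, 0),
    c("F3", 62, 123), c("F4", 62, 57), c("P3", 62, -123), c("P4", 62, -57),
    c("Fp1", 90, 108), c("Fp2", 90, 72), c("O1", 90, -108), c("O2", 90, -72),
    c("F7", 90, 144), c("F8", 90, 36), c("T5", 90, -144), c("T6", 90, -36),
    c("T3", 90, 180), c("T4", 90, 0)
  )
  incl <- as.numeric(tab[, 2]) * pi / 180
  az <- as.numeric(tab[, 3]) * pi / 180
  data.frame(label = tab[, 1],
             x = sin(incl) * cos(az),
             y = sin(incl) * sin(az),
             z = cos(incl),
             stringsAsFactors = FALSE)
}

#' Quasi-uniform high-density montage
#'
#' Deterministic Fibonacci-lattice electrode layout on the upper hemisphere
#' of a unit sphere, for simulating high-density acquisition systems.
#'
#' @param n number of electrodes.
#' @param prefix label prefix; labels are \code{E01, E02, ...}.
#' @return data.frame(label, x, y, z)
#' @export
fibonacciMontage <- function(n, prefix = "E") {
  i <- seq_len(n)
  ga <- pi * (3 - sqrt(5))
  z <- (i - 0.5) / n           # upper hemisphere only
  r <- sqrt(1 - z^2)
  th <- ga * i
  data.frame(label = sprintf("%s%02d", prefix, i),
             x = r * cos(th), y = r * sin(th), z = z,
             stringsAsFactors = FALSE)
}

# --- filtering -------------------------------------------------------------

# Zero-phase Butterworth filter applied along rows of a channels x samples
# matrix. type: "low", "high", "pass" (band), "stop".
butterZeroPhase <- function(x, rate, low = NULL, high = NULL,
                            order = 4, type = c("pass", "low", "high", "stop")) {
  type <- match.arg(type)
  nyq <- rate / 2
  filt <- switch(type,
    low = signal::butter(order, high / nyq, type = "low"),
    high = signal::butter(order, low / nyq, type = "high"),
    pass = signal::butter(order, c(low, high) / nyq, type = "pass"),
    stop = signal::butter(order, c(low, high) / nyq, type = "stop"))
  if (is.null(dim(x))) return(signal::filtfilt(filt, x))
  t(apply(x, 1, function(ch) signal::filtfilt(filt, ch)))
}

# Band-pass with a transparent degenerate path: low <= 0 -> low-pass only;
# high >= nyquist -> high-pass only; both degenerate -> identity.
bandpassMatrix <- function(x, rate, low, high, order = 4) {
  nyq <- rate / 2
  lowOff <- is.null(low) || low <= 0
  highOff <- is.null(high) || high >= nyq
  if (lowOff && highOff) return(x)
  if (lowOff) return(butterZeroPhase(x, rate, high = high, order = order, type = "low"))
  if (highOff) return(butterZeroPhase(x, rate, low = low, order = order, type = "high"))
  butterZeroPhase(x, rate, low = low, high = high, order = order, type = "pass")
}

# --- noise -----------------------------------------------------------------

# Pink (1/f power) noise via spectral shaping of white Gaussian noise,
# normalized to the requested standard deviation. Uses the current RNG
# stream so callers control the seed.
pinkNoise <- function(n, amplitude = 1) {
  if (amplitude <= 0 || n < 2) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                   # DC kept at weight of f=1
  f <- pmin(f, n - f + 1)                     # mirror for negative freqs
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (amplitude / s)
  x
}

# Derive a bounded child seed from a parent seed and a stream index,
# keeping results within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 2654435761) %% 2147483647)
}

md5OfFile <- function(path) unname(tools::md5sum(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
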