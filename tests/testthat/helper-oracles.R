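# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

rms <- function(a, b = 0) sqrt(mean((a - b)^2))

# Subtract the cross-channel mean at every sample (channels x samples),
# i.e. express a matrix in the average reference.
centerChannels <- function(m) sweep(m, 2, colMeans(m), "-")

# Textbook per-voxel t statistics (pooled-variance two-sample).
oracleT <- function(a, b) {
  # a, b: obs x voxels matrices
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  sp2 <- (colSums(sweep(a, 2, m1)^2) + colSums(sweep(b, 2, m2)^2)) /
    (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Recursive flood fill over a logical mask on a grid, orthogonal
# connectivity, optional same-sign constraint via a value array.
oracleComponents <- function(active, shape, values = NULL,
                             diagonal = FALSE) {
  n <- prod(shape)
  coords <- arrayInd(seq_len(n), shape)
  lab <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!active[start] || lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in seq_len(n)) {
        if (!active[w] || lab[w] != 0L) next
        dd <- abs(coords[v, ] - coords[w, ])
        adjacent <- if (diagonal) max(dd) == 1 else sum(dd) == 1
        if (!adjacent) next
        if (!is.null(values) && sign(values[v]) != sign(values[w])) next
        lab[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  lab
}

# Cluster measures from a labelling.
oracleMeasures <- function(lab, tvals) {
  ids <- setdiff(unique(lab), 0L)
  lapply(ids, function(k) {
    idx <- which(lab == k)
    list(indices = sort(idx), size = length(idx),
         maximum = max(abs(tvals[idx])), mass = sum(tvals[idx]))
  })
}

# Per-voxel cluster-value map (measure of the containing cluster).
oracleClusterMap <- function(tvals, shape, tcrit, measure) {
  active <- abs(tvals) > tcrit
  lab <- oracleComponents(active, shape, values = tvals)
  out <- numeric(length(tvals))
  for (cl in oracleMeasures(lab, tvals)) {
    val <- switch(measure, size = cl$size, maximum = cl$maximum,
                  mass = cl$mass)
    out[cl$indices] <- val
  }
  out
}

# Exhaustive unpaired max-statistic permutation null and cluster p-values.
oraclePermTest <- function(a, b, thresholdP, measure, shape) {
  n1 <- nrow(a); n <- n1 + nrow(b)
  X <- rbind(a, b)
  df <- n - 2
  tcrit <- qt(1 - thresholdP / 2, df)
  combos <- combn(n, n1)
  nullMax <- apply(combos, 2, function(ix) {
    tv <- oracleT(X[ix, , drop = FALSE], X[-ix, , drop = FALSE])
    mp <- oracleClusterMap(tv, shape, tcrit, measure)
    if (all(mp == 0)) 0 else max(abs(mp))
  })
  tv <- oracleT(a, b)
  lab <- oracleComponents(abs(tv) > tcrit, shape, values = tv)
  clusters <- oracleMeasures(lab, tv)
  ps <- vapply(clusters, function(cl) {
    obs <- abs(switch(measure, size = cl$size, maximum = cl$maximum,
                      mass = cl$mass))
    (1 + sum(nullMax >= obs)) / (1 + length(nullMax))
  }, 0)
  list(clusters = clusters, p = ps, null = nullMax)
}

# Tiny deterministic synthetic ERP recording for reuse in tests.
quickSynth <- function(seed = 1, duration = 30, nEvents = 15, noise = 5,
                       artifacts = list(), ...) {
  cfg <- synthConfig(duration = duration, nEvents = nEvents, noise = noise,
                     artifacts = artifacts, seed = seed, ...)
  c(genRecording(cfg), list(config = cfg))
}
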