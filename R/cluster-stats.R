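#' Voxel-wise t-statistic map
#'
#' Computes the two-sample (pooled variance) or paired t statistic at every
#' voxel of a multidimensional grid. Observations are stacked along the
#' first array dimension; the remaining dimensions form the voxel grid.
#'
#' @param groupA,groupB numeric arrays, observations x voxel grid; the
#'   voxel grids must agree. With \code{paired = TRUE} the observation
#'   counts must match and the statistic is the paired t of A - B.
#' @param paired paired or two-sample statistic.
#' @param dimNames names of the voxel dimensions (default dim1, dim2, ...).
#' @param dimCoordinates list of axis coordinate vectors.
#' @param tail "two", "pos" or "neg"; stored for downstream thresholding.
#' @return a [StatMap-class] with degrees of freedom recorded.
#' @export
statMap <- function(groupA, groupB, paired = FALSE, dimNames = NULL,
                    dimCoordinates = NULL, tail = "two") {
  a <- asObsArray(groupA); b <- asObsArray(groupB)
  da <- dim(a); db <- dim(b)
  if (!identical(da[-1], db[-1]))
    stop("shape error: voxel grids differ between groups", call. = FALSE)
  if (da[1] < 2 || db[1] < 2)
    stop("insufficient-data error: need >= 2 observations per group",
         call. = FALSE)
  shape <- da[-1]
  nvox <- prod(shape)
  Xa <- t(matrix(a, da[1], nvox))          # voxels x obs
  Xb <- t(matrix(b, db[1], nvox))
  if (paired) {
    if (da[1] != db[1])
      stop("shape error: paired groups need equal observation counts",
           call. = FALSE)
    X <- Xa - Xb
    assign <- rep(1L, da[1])
    df <- da[1] - 1
  } else {
    X <- cbind(Xa, Xb)
    assign <- c(rep(1L, da[1]), rep(0L, db[1]))
    df <- da[1] + db[1] - 2
  }
  t <- cpp_tstats(X, assign, paired)
  if (is.null(dimNames)) dimNames <- paste0("dim", seq_along(shape))
  if (is.null(dimCoordinates))
    dimCoordinates <- lapply(shape, seq_len)
  new("StatMap", values = array(t, shape), dimNames = dimNames,
      dimCoordinates = dimCoordinates, df = df, tail = tail)
}

asObsArray <- function(x) {
  if (is.null(dim(x))) stop("observations must carry a dim attribute")
  if (length(dim(x)) == 1) x <- matrix(x, dim(x), 1)
  x
}

#' Build a voxel adjacency relation
#'
#' Grid dimensions are connected by orthogonal (von Neumann) or
#' diagonal-inclusive (Moore / Chebyshev-1) neighborhoods. A declared
#' spatial dimension (sensors) instead uses distance-threshold neighbors
#' computed from 3D positions: voxels are adjacent along it when they
#' share all grid coordinates and their sensors lie within
#' \code{spatialRadius}.
#'
#' @param shape integer grid dimensions.
#' @param connectivity "orthogonal" or "diagonal".
#' @param spatialDim index of the sensor dimension, or NULL.
#' @param spatialPositions sensor positions (rows) for the spatial
#'   dimension; required when \code{spatialDim} is set.
#' @param spatialRadius neighbor radius for sensors.
#' @return an [Adjacency-class]; voxels are indexed 1..prod(shape) in
#'   column-major order.
#' @export
buildAdjacency <- function(shape, connectivity = c("orthogonal", "diagonal"),
                           spatialDim = NULL, spatialPositions = NULL,
                           spatialRadius = NULL) {
  connectivity <- match.arg(connectivity)
  shape <- as.integer(shape)
  if (!length(shape) || any(shape < 1))
    stop("configuration error: shape must be nonempty positive dims",
         call. = FALSE)
  if (!is.null(spatialDim) &&
      (is.null(spatialPositions) || is.null(spatialRadius)))
    stop("configuration error: spatial dimension declared without ",
         "positions/radius", call. = FALSE)
  n <- prod(shape)
  nd <- length(shape)
  coords <- arrayInd(seq_len(n), shape)
  gridDims <- setdiff(seq_len(nd), spatialDim)

  spatialNbr <- NULL
  if (!is.null(spatialDim)) {
    P <- as.matrix(spatialPositions)
    if (nrow(P) != shape[spatialDim])
      stop("configuration error: positions rows must match the spatial dim",
           call. = FALSE)
    D <- as.matrix(stats::dist(P))
    spatialNbr <- lapply(seq_len(nrow(P)), function(i)
      which(D[i, ] <= spatialRadius & seq_len(nrow(P)) != i))
  }

  neighbors <- vector("list", n)
  strides <- cumprod(c(1L, shape[-nd]))
  # offsets over grid dims
  offs <- list()
  if (length(gridDims)) {
    if (connectivity == "orthogonal") {
      for (d in gridDims) for (s in c(-1L, 1L)) {
        o <- integer(nd); o[d] <- s; offs[[length(offs) + 1]] <- o
      }
    } else {
      grids <- rep(list(-1:1), length(gridDims))
      combos <- as.matrix(expand.grid(grids))
      for (r in seq_len(nrow(combos))) {
        if (all(combos[r, ] == 0)) next
        o <- integer(nd); o[gridDims] <- combos[r, ]
        offs[[length(offs) + 1]] <- o
      }
    }
  }
  for (v in seq_len(n)) {
    cv <- coords[v, ]
    nb <- integer(0)
    for (o in offs) {
      cw <- cv + o
      if (all(cw >= 1 & cw <= shape))
        nb <- c(nb, 1L + sum((cw - 1L) * strides))
    }
    if (!is.null(spatialDim)) {
      for (s in spatialNbr[[cv[spatialDim]]]) {
        cw <- cv; cw[spatialDim] <- s
        nb <- c(nb, 1L + sum((cw - 1L) * strides))
      }
    }
    neighbors[[v]] <- sort(unique(nb))
  }
  desc <- paste0(connectivity,
                 if (!is.null(spatialDim))
                   sprintf(" + spatial(dim %d, r=%g)", spatialDim,
                           spatialRadius) else "")
  new("Adjacency", neighbors = neighbors, shape = shape, descriptor = desc)
}

tCritical <- function(thresholdP, df, tail) {
  if (tail == "two") stats::qt(1 - thresholdP / 2, df)
  else stats::qt(1 - thresholdP, df)
}

#' Find supra-threshold clusters
#'
#' Active voxels are those whose voxel-wise p-value (from the t statistic
#' with the map's df, per its tail) is below \code{thresholdP}. Clusters
#' are connected components of active voxels under the adjacency relation;
#' for two-tailed maps, positive and negative excursions cluster
#' separately.
#'
#' @param map a [StatMap-class].
#' @param thresholdP cluster-forming threshold, in (0, 1).
#' @param adjacency an [Adjacency-class] matching the map's grid.
#' @return list of clusters, each \code{list(indices, size, maximum, mass,
#'   sign, p_value)} (p_value is NA until permutation inference).
#' @export
findClusters <- function(map, thresholdP, adjacency) {
  if (thresholdP <= 0 || thresholdP >= 1)
    stop("configuration error: thresholdP must lie in (0, 1)", call. = FALSE)
  t <- as.vector(map@values)
  tcrit <- tCritical(thresholdP, map@df, map@tail)
  active <- switch(map@tail,
                   two = abs(t) > tcrit,
                   pos = t > tcrit,
                   neg = t < -tcrit)
  n <- length(t)
  seen <- logical(n)
  clusters <- list()
  for (v0 in seq_len(n)) {
    if (!active[v0] || seen[v0]) next
    pos <- t[v0] > 0
    stack <- v0; seen[v0] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      members <- c(members, v)
      for (w in adjacency@neighbors[[v]]) {
        if (active[w] && !seen[w] && (t[w] > 0) == pos) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    clusters[[length(clusters) + 1]] <-
      list(indices = sort(members), size = length(members),
           maximum = max(abs(t[members])), mass = sum(t[members]),
           sign = if (pos) 1 else -1, p_value = NA_real_)
  }
  clusters
}

#' Cluster summary measure
#'
#' @param cluster a cluster from [findClusters()].
#' @param map the [StatMap-class] it was found in.
#' @param kind "size" (active voxel count), "maximum" (largest absolute
#'   statistic) or "mass" (signed sum of statistics).
#' @return scalar measure.
#' @export
clusterMeasure <- function(cluster, map, kind = c("mass", "size", "maximum")) {
  kind <- match.arg(kind)
  if (!length(cluster$indices))
    stop("domain error: empty cluster", call. = FALSE)
  t <- as.vector(map@values)[cluster$indices]
  switch(kind, size = length(t), maximum = max(abs(t)), mass = sum(t))
}

measureCode <- function(kind) match(kind, c("size", "maximum", "mass")) - 1L
tailCode <- function(tail) match(tail, c("two", "pos", "neg")) - 1L

# Permutation assignment matrix. Unpaired: rows of 0/1 labels (1 = group
# A); exhaustive over all distinct splits when feasible. Paired: rows of
# +/-1 sign flips; exhaustive over all 2^n when feasible.
permAssignments <- function(n, n1, nPerm, seed, paired) {
  if (paired) {
    if (2^n <= nPerm) {
      m <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
      dimnames(m) <- NULL
      return(list(assign = m, exhaustive = TRUE))
    }
    set.seed(seed)
    m <- matrix(sample(c(-1L, 1L), nPerm * n, replace = TRUE), nPerm, n)
    return(list(assign = m, exhaustive = FALSE))
  }
  if (choose(n, n1) <= nPerm) {
    combos <- utils::combn(n, n1)
    m <- matrix(0L, ncol(combos), n)
    for (i in seq_len(ncol(combos))) m[i, combos[, i]] <- 1L
    return(list(assign = m, exhaustive = TRUE))
  }
  set.seed(seed)
  m <- matrix(0L, nPerm, n)
  for (i in seq_len(nPerm)) m[i, sample.int(n, n1)] <- 1L
  list(assign = m, exhaustive = FALSE)
}

# Add-one permutation p-value; a relative tie tolerance keeps null
# replicates that equal the observed measure (e.g. the identity
# permutation in exhaustive mode) counted despite floating-point noise.
permPValue <- function(null, obs) {
  eps <- 1e-8 * (1 + abs(obs))
  (1 + sum(null >= obs - eps)) / (1 + length(null))
}

prepareGroups <- function(groupA, groupB, paired) {
  a <- asObsArray(groupA); b <- asObsArray(groupB)
  da <- dim(a); db <- dim(b)
  if (!identical(da[-1], db[-1]))
    stop("shape error: voxel grids differ between groups", call. = FALSE)
  if (da[1] < 2 || db[1] < 2)
    stop("insufficient-data error: need >= 2 observations per group",
         call. = FALSE)
  shape <- da[-1]
  nvox <- prod(shape)
  Xa <- t(matrix(a, da[1], nvox)); Xb <- t(matrix(b, db[1], nvox))
  if (paired) {
    if (da[1] != db[1])
      stop("shape error: paired groups need equal observation counts",
           call. = FALSE)
    list(X = Xa - Xb, n = da[1], n1 = da[1], df = da[1] - 1, shape = shape)
  } else {
    list(X = cbind(Xa, Xb), n = da[1] + db[1], n1 = da[1],
         df = da[1] + db[1] - 2, shape = shape)
  }
}

#' Cluster-based max-statistic permutation test
#'
#' Family-wise-error-controlling cluster inference: the observed clusters'
#' measures are compared against the permutation distribution of the
#' maximum cluster measure (over both excursion signs) under label
#' reshuffling (unpaired) or sign flipping (paired). When the number of
#' distinct permutations does not exceed \code{nPerm}, the null is
#' enumerated exhaustively; otherwise \code{nPerm} random permutations are
#' drawn (deterministic per seed). Cluster p-values use the add-one
#' estimator \code{(1 + #(null >= observed)) / (1 + #null)}.
#'
#' @inheritParams statMap
#' @param thresholdP cluster-forming threshold (voxel-wise p).
#' @param measure "mass", "size" or "maximum".
#' @param nPerm number of permutations (floor 100).
#' @param seed integer seed for sampled permutations.
#' @param adjacency an [Adjacency-class] over the voxel grid.
#' @param tail "two", "pos" or "neg".
#' @return list: \code{clusters} (with p-values), \code{null} (max-measure
#'   distribution), \code{map} (the observed [StatMap-class]),
#'   \code{exhaustive}, \code{nPerm}, \code{measure}, \code{thresholdP}.
#' @export
permutationTest <- function(groupA, groupB, thresholdP = 0.05,
                            measure = "mass", nPerm = 1000, seed = 1,
                            adjacency, paired = FALSE, tail = "two") {
  if (nPerm < 100)
    stop("configuration error: nPerm must be >= 100", call. = FALSE)
  g <- prepareGroups(groupA, groupB, paired)
  map <- statMap(groupA, groupB, paired = paired, tail = tail)
  clusters <- findClusters(map, thresholdP, adjacency)
  tcrit <- tCritical(thresholdP, g$df, tail)
  pa <- permAssignments(g$n, g$n1, nPerm, seed, paired)
  null <- cpp_null_max(g$X, pa$assign, paired, tcrit, tailCode(tail),
                       measureCode(measure), adjacency@neighbors)
  for (i in seq_along(clusters)) {
    obs <- abs(clusterMeasure(clusters[[i]], map, measure))
    clusters[[i]]$p_value <- permPValue(null, obs)
  }
  list(clusters = clusters, null = null, map = map,
       exhaustive = pa$exhaustive, nPerm = length(null),
       measure = measure, thresholdP = thresholdP)
}

#' Default threshold grid for threshold-averaged cluster inference
#'
#' Eight cluster-forming p thresholds spanning the conventional range
#' 0.05 down to 0.0001, strictly decreasing.
#'
#' @return numeric vector.
#' @export
defaultThresholdGrid <- function() {
  c(0.05, 0.02, 0.01, 0.005, 0.002, 0.001, 0.0005, 0.0001)
}

#' Threshold-free averaged cluster estimation
#'
#' Removes the user-chosen cluster-forming threshold by computing the
#' cluster-value map (each voxel assigned the measure of the cluster
#' containing it, 0 when inactive) at every threshold of a grid and
#' averaging the maps voxel-wise. Inference is max-statistic permutation
#' on the averaged map: the null is the permutation distribution of the
#' maximum absolute averaged cluster value, and each voxel's p-value uses
#' the add-one estimator. Deterministic per seed.
#'
#' @inheritParams permutationTest
#' @param thresholdGrid cluster-forming p thresholds; sorted to be
#'   strictly decreasing, length >= 1.
#' @return object of class \code{"uceResult"}: list with
#'   \code{thresholdGrid}, \code{perThresholdMaps} (voxels x thresholds),
#'   \code{averagedMap} (array on the voxel grid), \code{pValues} (array),
#'   \code{null}, \code{nPerm}, \code{seed}, \code{map}.
#' @export
uceTest <- function(groupA, groupB, thresholdGrid = defaultThresholdGrid(),
                    measure = "mass", nPerm = 1000, seed = 1, adjacency,
                    paired = FALSE, tail = "two") {
  thresholdGrid <- sort(unique(thresholdGrid), decreasing = TRUE)
  if (!length(thresholdGrid))
    stop("configuration error: threshold grid is empty", call. = FALSE)
  if (any(thresholdGrid <= 0 | thresholdGrid >= 1))
    stop("configuration error: thresholds must lie in (0, 1)", call. = FALSE)
  g <- prepareGroups(groupA, groupB, paired)
  map <- statMap(groupA, groupB, paired = paired, tail = tail)
  tcrits <- vapply(thresholdGrid, tCritical, 0, df = g$df, tail = tail)
  tv <- as.vector(map@values)
  per <- vapply(tcrits, function(tc)
    cpp_cluster_map(tv, tc, tailCode(tail), measureCode(measure),
                    adjacency@neighbors),
    numeric(length(tv)))
  avg <- rowMeans(per)
  pa <- permAssignments(g$n, g$n1, nPerm, seed, paired)
  null <- cpp_uce_null_max(g$X, pa$assign, paired, tcrits, tailCode(tail),
                           measureCode(measure), adjacency@neighbors)
  pv <- vapply(abs(avg), function(o) permPValue(null, o), 0)
  structure(list(thresholdGrid = thresholdGrid,
                 perThresholdMaps = per,
                 averagedMap = array(avg, g$shape),
                 pValues = array(pv, g$shape),
                 null = null, nPerm = length(null), seed = seed,
                 exhaustive = pa$exhaustive, measure = measure, map = map),
            class = "uceResult")
}

#' Bonferroni reference correction
#'
#' Voxel-wise Bonferroni adjustment, provided as the conservative
#' reference against which cluster-based results can be compared.
#'
#' @param pValues numeric vector/array of voxel p-values.
#' @return adjusted p-values, same shape.
#' @export
bonferroniCorrect <- function(pValues) {
  out <- stats::p.adjust(as.vector(pValues), method = "bonferroni")
  if (!is.null(dim(pValues))) dim(out) <- dim(pValues)
  out
}
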