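test_that("identical groups give an all-zero statistic map", {
  set.seed(1)
  a <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  m <- statMap(a, a)
  expect_true(all(m@values == 0))
  expect_equal(m@df, 4)
})

test_that("a 2x2 hand example reproduces the textbook t value", {
  a <- matrix(c(1, 3), 2, 1)
  b <- matrix(c(2, 4), 2, 1)
  m <- statMap(a, b)
  expect_equal(as.vector(m@values), -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m@df, 2)
})

test_that("statistic maps match the per-voxel textbook formula", {
  set.seed(2)
  a <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  b <- array(rnorm(4 * 5 * 5, 0.3), c(4, 5, 5))
  m <- statMap(a, b)
  expect_equal(as.vector(m@values),
               as.vector(oracleT(matrix(a, 4), matrix(b, 4))),
               tolerance = 1e-12)
  # paired route: t of the differences
  mp <- statMap(a, b, paired = TRUE)
  d <- matrix(a, 4) - matrix(b, 4)
  tPaired <- colMeans(d) / (apply(d, 2, sd) / sqrt(4))
  expect_equal(as.vector(mp@values), tPaired, tolerance = 1e-12)
  expect_equal(mp@df, 3)
  expect_error(statMap(a, array(rnorm(4 * 6), c(4, 6))), "shape error")
})

test_that("grid adjacencies match enumeration", {
  expect_length(buildAdjacency(c(1, 1))@neighbors[[1]], 0)

  adj22 <- buildAdjacency(c(2, 2))
  expect_equal(sum(lengths(adj22@neighbors)) / 2, 4)

  adj <- buildAdjacency(c(3, 4), connectivity = "diagonal")
  coords <- arrayInd(1:12, c(3, 4))
  for (v in 1:12) {
    expected <- which(vapply(1:12, function(w)
      w != v && max(abs(coords[v, ] - coords[w, ])) == 1, TRUE))
    expect_equal(adj@neighbors[[v]], expected)
  }
})

test_that("a sensor dimension uses distance-threshold neighborhoods", {
  pos <- as.matrix(montage1020()[1:5, c("x", "y", "z")])
  expect_error(buildAdjacency(c(3, 5), spatialDim = 2),
               "configuration error")
  adj <- buildAdjacency(c(3, 5), spatialDim = 2, spatialPositions = pos,
                        spatialRadius = 1.2)
  D <- as.matrix(dist(pos))
  # voxel (1, s) and (1, s2) adjacent iff sensors within radius
  for (s1 in 1:5) for (s2 in 1:5) {
    v <- 1 + (s1 - 1) * 3; w <- 1 + (s2 - 1) * 3
    expect_equal(w %in% adj@neighbors[[v]],
                 s1 != s2 && D[s1, s2] <= 1.2)
  }
})

test_that("clusters of planted blobs are found exactly", {
  adj <- buildAdjacency(c(5, 5))
  vals <- array(0, c(5, 5))
  vals[1:3, 1] <- 5                    # blob of 3
  vals[3:4, 4:5] <- 5                  # blob of 4
  m <- new("StatMap", values = vals, dimNames = c("a", "b"),
           dimCoordinates = list(1:5, 1:5), df = 20, tail = "two")
  cl <- findClusters(m, 0.05, adj)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, 0, "size"), c(3, 4))

  m0 <- new("StatMap", values = array(0, c(5, 5)), dimNames = c("a", "b"),
            dimCoordinates = list(1:5, 1:5), df = 20, tail = "two")
  expect_length(findClusters(m0, 0.05, adj), 0)
})

test_that("connected components equal the flood-fill oracle on random masks", {
  adj <- buildAdjacency(c(4, 4))
  set.seed(3)
  for (k in 1:200) {
    active <- runif(16) < 0.4
    vals <- array(ifelse(active, 6, 0), c(4, 4))
    m <- new("StatMap", values = vals, dimNames = c("a", "b"),
             dimCoordinates = list(1:4, 1:4), df = 10, tail = "two")
    cl <- findClusters(m, 0.05, adj)
    lab <- oracleComponents(active, c(4, 4))
    orc <- oracleMeasures(lab, as.vector(vals))
    expect_equal(length(cl), length(orc))
    got <- lapply(cl, `[[`, "indices")
    want <- lapply(orc, `[[`, "indices")
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("cluster measures are size, max |t| and signed mass", {
  vals <- array(c(2, 3, 4, 0), c(2, 2))
  m <- new("StatMap", values = vals, dimNames = c("a", "b"),
           dimCoordinates = list(1:2, 1:2), df = 1000, tail = "two")
  adj <- buildAdjacency(c(2, 2))
  cl <- findClusters(m, 0.05, adj)[[1]]
  expect_equal(clusterMeasure(cl, m, "size"), 3)
  expect_equal(clusterMeasure(cl, m, "maximum"), 4)
  expect_equal(clusterMeasure(cl, m, "mass"), 9)
  expect_error(clusterMeasure(list(indices = integer()), m, "mass"),
               "domain error")

  single <- new("StatMap", values = array(c(2.5, 0, 0, 0), c(2, 2)),
                dimNames = c("a", "b"), dimCoordinates = list(1:2, 1:2),
                df = 30, tail = "two")
  c1 <- findClusters(single, 0.05, adj)[[1]]
  expect_equal(clusterMeasure(c1, single, "size"), 1)
  expect_equal(clusterMeasure(c1, single, "mass"), 2.5)

  set.seed(4)
  vals <- array(rnorm(16, 0, 3), c(4, 4))
  mr <- new("StatMap", values = vals, dimNames = c("a", "b"),
            dimCoordinates = list(1:4, 1:4), df = 30, tail = "two")
  for (cl in findClusters(mr, 0.05, buildAdjacency(c(4, 4))))
    expect_equal(clusterMeasure(cl, mr, "mass"),
                 sum(as.vector(vals)[cl$indices]))
})

test_that("2+2 observations use the exhaustive null of all 6 splits", {
  set.seed(5)
  a <- matrix(rnorm(2 * 4, 2), 2, 4); dim(a) <- c(2, 2, 2)
  b <- matrix(rnorm(2 * 4), 2, 4); dim(b) <- c(2, 2, 2)
  adj <- buildAdjacency(c(2, 2))
  pt <- permutationTest(a, b, thresholdP = 0.3, measure = "mass",
                        nPerm = 100, seed = 1, adjacency = adj)
  expect_true(pt$exhaustive)
  expect_equal(pt$nPerm, 6)
  for (cl in pt$clusters)
    expect_true(round(cl$p_value * 7) == cl$p_value * 7)
})

test_that("exhaustive p-values are invariant to observation order", {
  set.seed(6)
  a <- array(rnorm(3 * 9, 1.5), c(3, 3, 3))
  b <- array(rnorm(3 * 9), c(3, 3, 3))
  adj <- buildAdjacency(c(3, 3))
  p1 <- permutationTest(a, b, 0.1, "mass", 100, 1, adj)
  perm <- c(2, 3, 1)
  p2 <- permutationTest(a[perm, , , drop = FALSE],
                        b[c(3, 1, 2), , , drop = FALSE], 0.1, "mass",
                        100, 1, adj)
  expect_equal(sort(vapply(p1$clusters, `[[`, 0, "p_value")),
               sort(vapply(p2$clusters, `[[`, 0, "p_value")))
})

test_that("permutation inference matches the brute-force oracle exactly", {
  set.seed(7)
  for (k in 1:5) {
    a <- array(rnorm(3 * 16, 1), c(3, 4, 4))
    b <- array(rnorm(4 * 16), c(4, 4, 4))
    adj <- buildAdjacency(c(4, 4))
    for (measure in c("size", "maximum", "mass")) {
      pt <- permutationTest(a, b, 0.2, measure, 100, 1, adj)
      orc <- oraclePermTest(matrix(a, 3), matrix(b, 4), 0.2, measure,
                            c(4, 4))
      expect_true(pt$exhaustive)
      expect_equal(sort(pt$null), sort(orc$null), tolerance = 1e-10)
      expect_equal(sort(vapply(pt$clusters, `[[`, 0, "p_value")),
                   sort(orc$p), tolerance = 1e-10)
    }
  }
})

test_that("a planted strong effect reaches significance", {
  set.seed(8)
  a <- array(rnorm(15 * 8 * 8), c(15, 8, 8))
  a[, 3:5, 3:5] <- a[, 3:5, 3:5] + 3        # Cohen's d = 3 block
  b <- array(rnorm(15 * 8 * 8), c(15, 8, 8))
  adj <- buildAdjacency(c(8, 8))
  pt <- permutationTest(a, b, 0.05, "mass", nPerm = 500, seed = 2,
                        adjacency = adj)
  expect_lt(min(vapply(pt$clusters, `[[`, 0, "p_value")), 0.01)
})

test_that("permutation p-values are deterministic per seed", {
  set.seed(9)
  a <- array(rnorm(8 * 25, 0.8), c(8, 5, 5))
  b <- array(rnorm(8 * 25), c(8, 5, 5))
  adj <- buildAdjacency(c(5, 5))
  p1 <- permutationTest(a, b, 0.05, "mass", 300, 7, adj)
  p2 <- permutationTest(a, b, 0.05, "mass", 300, 7, adj)
  expect_identical(vapply(p1$clusters, `[[`, 0, "p_value"),
                   vapply(p2$clusters, `[[`, 0, "p_value"))
  expect_identical(p1$null, p2$null)
  u1 <- uceTest(a, b, nPerm = 300, seed = 7, adjacency = adj)
  u2 <- uceTest(a, b, nPerm = 300, seed = 7, adjacency = adj)
  expect_identical(u1$pValues, u2$pValues)
})

test_that("shrinking the threshold never grows a cluster", {
  set.seed(10)
  a <- array(rnorm(10 * 36, 0.8), c(10, 6, 6))
  b <- array(rnorm(10 * 36), c(10, 6, 6))
  m <- statMap(a, b)
  adj <- buildAdjacency(c(6, 6))
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.001), function(p) {
    cl <- findClusters(m, p, adj)
    if (length(cl)) max(vapply(cl, `[[`, 0, "size")) else 0
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a one-threshold grid reduces the averaged map to the plain cluster-value map", {
  set.seed(11)
  a <- array(rnorm(6 * 16, 1), c(6, 4, 4))
  b <- array(rnorm(6 * 16), c(6, 4, 4))
  adj <- buildAdjacency(c(4, 4))
  u <- uceTest(a, b, thresholdGrid = 0.05, measure = "mass", nPerm = 200,
               seed = 3, adjacency = adj)
  tv <- as.vector(statMap(a, b)@values)
  tcrit <- qt(1 - 0.05 / 2, 10)
  expect_identical(as.vector(u$averagedMap),
                   oracleClusterMap(tv, c(4, 4), tcrit, "mass"))
})

test_that("a two-threshold grid equals the hand-composed oracle mean", {
  set.seed(12)
  a <- array(rnorm(6 * 16, 1.2), c(6, 4, 4))
  b <- array(rnorm(6 * 16), c(6, 4, 4))
  adj <- buildAdjacency(c(4, 4))
  u <- uceTest(a, b, thresholdGrid = c(0.05, 0.01), measure = "mass",
               nPerm = 200, seed = 3, adjacency = adj)
  tv <- as.vector(statMap(a, b)@values)
  m1 <- oracleClusterMap(tv, c(4, 4), qt(1 - 0.05 / 2, 10), "mass")
  m2 <- oracleClusterMap(tv, c(4, 4), qt(1 - 0.01 / 2, 10), "mass")
  expect_equal(as.vector(u$averagedMap), (m1 + m2) / 2, tolerance = 1e-12)
  # averaged map = arithmetic mean of the stored per-threshold maps, exact
  expect_identical(as.vector(u$averagedMap), rowMeans(u$perThresholdMaps))
  expect_true(all(diff(u$thresholdGrid) < 0))
  expect_error(uceTest(a, b, thresholdGrid = numeric(), adjacency = adj),
               "configuration error")
})

test_that("single-threshold cluster counts vary while the averaged test needs no threshold", {
  # graded effects: two solid blobs joined by a weaker bridge, so the
  # lenient threshold sees one merged cluster, stricter ones see two, and
  # the strictest sees none
  set.seed(13)
  n <- 14
  a <- array(rnorm(n * 12 * 12), c(n, 12, 12))
  a[, 3:5, 3:5] <- a[, 3:5, 3:5] + 1.5
  a[, 8:10, 3:5] <- a[, 8:10, 3:5] + 1.5
  a[, 6:7, 4] <- a[, 6:7, 4] + 0.9
  b <- array(rnorm(n * 12 * 12), c(n, 12, 12))
  adj <- buildAdjacency(c(12, 12))
  nsig <- vapply(c(0.05, 0.01, 0.001, 0.0001), function(thr) {
    pt <- permutationTest(a, b, thr, "mass", nPerm = 300, seed = 4,
                          adjacency = adj)
    sum(vapply(pt$clusters, `[[`, 0, "p_value") < 0.05)
  }, 0)
  expect_gt(length(unique(nsig)), 1)
  u <- uceTest(a, b, measure = "mass", nPerm = 300, seed = 4,
               adjacency = adj)
  expect_s3_class(u, "uceResult")
  expect_true(any(u$pValues < 0.05))
})

test_that("degenerate groups are rejected", {
  a <- array(rnorm(1 * 4), c(1, 2, 2))
  b <- array(rnorm(5 * 4), c(5, 2, 2))
  expect_error(permutationTest(a, b, adjacency = buildAdjacency(c(2, 2))),
               "insufficient-data")
})

test_that("Bonferroni reference correction matches p.adjust", {
  p <- array(c(0.01, 0.2, 0.004, 0.5), c(2, 2))
  expect_equal(as.vector(bonferroniCorrect(p)),
               p.adjust(as.vector(p), "bonferroni"))
})
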