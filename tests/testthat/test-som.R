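# Kohonen map engine: normalization, winner search, neighborhood, training.

test_that("normalizeColumns min-maps columns and flags degenerate ones", {
  nm <- normalizeColumns(cbind(a = c(0, 5, 10), b = c(7, 7, 7)))
  expect_equal(unname(nm$data[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm$data[, "b"]), c(0.5, 0.5, 0.5))
  expect_equal(nm$scale$constant, c(FALSE, TRUE))
  expect_equal(nm$scale$feature, c("a", "b"))
})

test_that("normalization round-trips random matrices within round-off", {
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(60, sd = 10 * i), 12, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    nm <- normalizeColumns(x)
    expect_true(all(nm$data >= 0 & nm$data <= 1))
    expect_equal(denormalizeColumns(nm$data, nm$scale), x, tolerance = 1e-12)
  }
})

test_that("normalizeColumns names the offending cell", {
  x <- matrix(c(1, NA, 3, 4), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(normalizeColumns(x), "row 'r2', column 'c1'")
})

test_that("winner matches identity and tie-break conventions", {
  m <- randomModel(4, 5, 3, seed = 2)
  w <- winnerNeuron(m, somWeights(m)[(2 - 1) * 5 + 3, ])
  expect_equal(c(w$row, w$col), c(2, 3))
  expect_equal(w$distance, 0)

  # two identical nearest weight vectors: smaller row-major index wins
  W <- matrix(0.9, 4, 2)
  W[2, ] <- c(0.1, 0.1)
  W[3, ] <- c(0.1, 0.1)
  tied <- new("SOMModel", grid = gridSpec(2, 2), weights = W,
              featureNames = c("f1", "f2"), config = trainConfig(),
              trained = TRUE)
  expect_equal(winnerNeuron(tied, c(0.1, 0.1))$index, 2)
})

test_that("winner equals the exhaustive brute-force oracle on 100 instances", {
  set.seed(33)
  for (i in 1:100) {
    nx <- sample(1:6, 1)
    ny <- sample(1:6, 1)
    nf <- sample(1:8, 1)
    m <- randomModel(nx, ny, nf, seed = 1000 + i)
    x <- stats::runif(nf)
    got <- winnerNeuron(m, x)
    ref <- naiveWinner(somWeights(m), x)
    expect_identical(got$index, ref$index)
    expect_equal(got$distance, ref$distance, tolerance = 1e-14)
  }
})

test_that("winner rejects dimension mismatch", {
  m <- randomModel(2, 2, 3, seed = 5)
  expect_error(winnerNeuron(m, c(0.1, 0.2)), "features")
})

test_that("topoDistance is the Chebyshev grid metric", {
  g <- gridSpec(5, 5)
  expect_equal(topoDistance(g, c(2, 2), c(2, 2)), 0)
  expect_equal(topoDistance(g, c(1, 1), c(3, 4)), 3)
  set.seed(7)
  for (i in 1:20) {
    a <- c(sample(1:5, 1), sample(1:5, 1))
    b <- c(sample(1:5, 1), sample(1:5, 1))
    expect_equal(topoDistance(g, a, b), topoDistance(g, b, a))
  }
  expect_error(topoDistance(g, c(0, 1), c(1, 1)), "out of grid")
})

test_that("neighborhoodWeight is triangular with the stated values", {
  expect_equal(neighborhoodWeight(0, 2), 1)
  expect_equal(neighborhoodWeight(3, 2), 0)
  expect_equal(neighborhoodWeight(1, 1), 0.5)
  expect_error(neighborhoodWeight(-1, 2), "non-negative")
  # non-increasing in d, non-decreasing in radius
  for (r in c(0, 1, 2.5, 4)) {
    w <- neighborhoodWeight(0:6, r)
    expect_true(all(diff(w) <= 0))
  }
  for (d in 0:4) {
    w <- vapply(c(0, 1, 2, 3.5, 5), function(r) neighborhoodWeight(d, r),
                numeric(1))
    expect_true(all(diff(w) >= -1e-15))
  }
})

test_that("a 1x1 map trained on a repeated point converges to it", {
  x <- matrix(rep(c(0.3, 0.7, 0.1), each = 5), 5, 3)
  m <- trainSOM(x, gridSpec(1, 1),
                trainConfig(epochs = 100, radiusStart = 0, seed = 4))
  expect_lt(max(abs(somWeights(m)[1, ] - c(0.3, 0.7, 0.1))), 1e-3)
})

test_that("a 2x1 map splits two well-separated clusters onto its neurons", {
  tc <- makeTwoClusters(nPer = 20, d = 3, seed = 9)
  m <- trainSOM(tc$x, gridSpec(2, 1),
                trainConfig(epochs = 60, radiusEnd = 0, seed = 10))
  mp <- mapObjects(m, tc$x)
  # clusters land on different neurons...
  byCluster <- split(mp$index, tc$label)
  expect_length(unique(byCluster[[1]]), 1)
  expect_length(unique(byCluster[[2]]), 1)
  expect_false(byCluster[[1]][1] == byCluster[[2]][1])
  # ...and each weight sits within noise of its cluster mean
  for (cl in 1:2) {
    mu <- colMeans(tc$x[tc$label == cl, ])
    expect_lt(max(abs(somWeights(m)[byCluster[[cl]][1], ] - mu)), 0.05)
  }
})

test_that("training is bit-deterministic under the seed", {
  tc <- makeTwoClusters(nPer = 10, d = 4, seed = 3)
  cfg <- trainConfig(epochs = 25, seed = 99)
  m1 <- trainSOM(tc$x, gridSpec(3, 3), cfg)
  m2 <- trainSOM(tc$x, gridSpec(3, 3), cfg)
  expect_identical(somWeights(m1), somWeights(m2))
  expect_identical(mapObjects(m1, tc$x), mapObjects(m2, tc$x))
  m3 <- trainSOM(tc$x, gridSpec(3, 3), trainConfig(epochs = 25, seed = 100))
  expect_false(identical(somWeights(m1), somWeights(m3)))
})

test_that("compiled training equals a naive R reimplementation", {
  set.seed(21)
  X <- matrix(stats::runif(8 * 3), 8, 3)
  cfg <- trainConfig(epochs = 5, seed = 77)
  grid <- gridSpec(2, 3)
  m <- trainSOM(X, grid, cfg)
  init <- fdQSAR:::.somInit(6, 3, 0, 8, 5, 77)
  etas <- seq(0.5, 0.01, length.out = 5)
  radii <- seq(max(2, 3) - 1, 0, length.out = 5)
  ref <- naiveTrain(X, init$W0y, init$W0x, init$W0y, init$orders,
                    etas, radii, 2, 3)
  expect_equal(somWeights(m), ref$Wx, tolerance = 1e-13)
})

test_that("trained weights stay within [-0.1, 1.1] on normalized data", {
  tc <- makeTwoClusters(nPer = 25, d = 5, seed = 14)
  m <- trainSOM(tc$x, gridSpec(4, 4), trainConfig(epochs = 40, seed = 6))
  expect_true(all(somWeights(m) >= -0.1 & somWeights(m) <= 1.1))
})

test_that("unnormalized data is rejected with advice", {
  x <- matrix(c(0.2, 5, 0.4, 0.5), 2, 2)
  expect_error(trainSOM(x, gridSpec(2, 2)), "normalizeColumns")
})

test_that("mapObjects is per-object, order-invariant, and QE-consistent", {
  tc <- makeTwoClusters(nPer = 12, d = 3, seed = 8)
  m <- trainSOM(tc$x, gridSpec(3, 3), trainConfig(epochs = 30, seed = 12))
  mp <- mapObjects(m, tc$x)
  # equals winnerNeuron applied independently
  for (i in c(1, 7, 20)) {
    w <- winnerNeuron(m, tc$x[i, ])
    expect_equal(mp$index[i], w$index)
    expect_equal(mp$distance[i], w$distance)
  }
  # permutation invariance
  perm <- sample(nrow(tc$x))
  mpPerm <- mapObjects(m, tc$x[perm, ])
  expect_equal(mpPerm$index, mp$index[perm])
  expect_equal(mpPerm$distance, mp$distance[perm])
  # mean mapped distance is the quantization error by definition
  expect_equal(mean(mp$distance), quantizationError(m, tc$x))
  # mapping the model's own weights gives zero distances
  mw <- mapObjects(m, somWeights(m))
  expect_true(all(mw$distance < 1e-12))
})

test_that("training reduces quantization error vs. random init on >=90% of seeds", {
  tc <- makeTwoClusters(nPer = 15, d = 4, seed = 5)
  wins <- 0
  for (s in 1:20) {
    trained <- trainSOM(tc$x, gridSpec(3, 3),
                        trainConfig(epochs = 30, seed = s))
    untrained <- randomModel(3, 3, 4, seed = s)
    if (quantizationError(trained, tc$x) <=
        quantizationError(untrained, tc$x)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("co-mapped objects are mutually closer than cross-neuron pairs", {
  ok <- 0
  for (s in 1:10) {
    tc <- makeTwoClusters(nPer = 12, d = 4, seed = 100 + s)
    m <- trainSOM(tc$x, gridSpec(3, 3), trainConfig(epochs = 30, seed = s))
    mp <- mapObjects(m, tc$x)
    D <- as.matrix(stats::dist(tc$x))
    same <- outer(mp$index, mp$index, "==") & upper.tri(D)
    cross <- (!outer(mp$index, mp$index, "==")) & upper.tri(D)
    if (sum(same) > 0 && sum(cross) > 0 &&
        mean(D[same]) < mean(D[cross])) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("quantizationError rejects empty data", {
  m <- randomModel(2, 2, 3, seed = 1)
  expect_error(quantizationError(m, matrix(numeric(0), 0, 3)), "at least one")
})
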