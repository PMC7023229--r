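# Counter-propagation network: training, lookup prediction, fit metrics,
# leave-one-out cross-validation.

test_that("a single training object becomes a lookup entry", {
  X <- matrix(c(0.2, 0.8), 1, 2)
  y <- 0.6
  m <- trainCPANN(X, y, gridSpec(2, 2), trainConfig(epochs = 100, seed = 3))
  expect_lt(abs(unname(predict(m, X[1, ])) - 0.6), 1e-3)
})

test_that("a 1x1 grid absorbs all corrections toward mean(y)", {
  set.seed(15)
  X <- matrix(stats::runif(100 * 2), 100, 2)
  y <- stats::runif(100)
  m <- trainCPANN(X, y, gridSpec(1, 1),
                  trainConfig(epochs = 100, radiusStart = 0, seed = 8))
  expect_lt(abs(outputWeights(m)[1, 1] - mean(y)), 0.05)
})

test_that("distinct objects fewer than neurons reach the lookup-table limit", {
  set.seed(16)
  X <- matrix(stats::runif(8 * 3), 8, 3)
  y <- stats::runif(8)
  # long training with a non-vanishing late learning rate pins each object
  # onto its own neuron's lookup entry
  m <- trainCPANN(X, y, gridSpec(4, 4),
                  trainConfig(epochs = 1000, etaEnd = 0.05, radiusEnd = 0,
                              seed = 2))
  fm <- fitMetrics(y, predict(m, X))
  expect_gte(fm$r2, 0.99)
})

test_that("prediction is an output-layer lookup of the input-layer winner", {
  set.seed(17)
  X <- matrix(stats::runif(30 * 3), 30, 3)
  y <- stats::runif(30)
  m <- trainCPANN(X, y, gridSpec(3, 3), trainConfig(epochs = 40, seed = 5))
  # querying an input weight vector returns that neuron's output weight
  for (n in c(1, 5, 9)) {
    expect_equal(unname(predict(m, somWeights(m)[n, ])),
                 outputWeights(m)[n, 1])
  }
  # lookup property: at most nx*ny distinct predictions over any query set
  q <- matrix(stats::runif(500 * 3), 500, 3)
  expect_lte(length(unique(predict(m, q)[, 1])), 9)
  # equals the brute-force winner + lookup oracle
  for (i in 1:20) {
    ref <- naiveWinner(somWeights(m), q[i, ])
    expect_equal(unname(predict(m, q[i, ])),
                 outputWeights(m)[ref$index, 1])
  }
  # purity: repeated calls are identical
  expect_identical(predict(m, q), predict(m, q))
})

test_that("predict rejects dimension mismatch", {
  m <- trainCPANN(matrix(stats::runif(12), 4, 3), stats::runif(4),
                  gridSpec(2, 2), trainConfig(epochs = 10, seed = 1))
  expect_error(predict(m, c(0.1, 0.2)), "features")
})

test_that("trainCPANN validates row alignment and target range", {
  X <- matrix(stats::runif(12), 4, 3)
  expect_error(trainCPANN(X, stats::runif(3), gridSpec(2, 2)),
               "row-aligned")
  expect_error(trainCPANN(X, c(0.2, 0.3, 1.7, 0.1), gridSpec(2, 2)),
               "normalize")
})

test_that("input and output layers get the same neighborhood updates", {
  set.seed(22)
  X <- matrix(stats::runif(10 * 2), 10, 2)
  y <- matrix(stats::runif(10), 10, 1)
  cfg <- trainConfig(epochs = 6, seed = 31)
  m <- trainCPANN(X, y[, 1], gridSpec(2, 2), cfg)
  init <- fdQSAR:::.somInit(4, 2, 1, 10, 6, 31)
  etas <- seq(0.5, 0.01, length.out = 6)
  radii <- seq(1, 0, length.out = 6)
  ref <- naiveTrain(X, y, init$W0x, init$W0y, init$orders, etas, radii, 2, 2)
  expect_equal(somWeights(m), ref$Wx, tolerance = 1e-13)
  expect_equal(outputWeights(m), ref$Wy, tolerance = 1e-13)
})

test_that("fitMetrics matches the definitional formulas", {
  fm <- fitMetrics(c(0, 1, 2), c(0, 1, 5))
  expect_equal(fm$r2, 25 / 28)        # (cov 5 / sqrt(2 * 14))^2
  expect_equal(fm$rmse, sqrt(3))      # sqrt((0 + 0 + 9) / 3)
  expect_equal(fm$n, 3)
  expect_equal(fm$r2ss, 1 - 9 / 2)

  perfect <- fitMetrics(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  # r2 is invariant to affine rescaling of predictions; rmse is not
  obs <- c(1, 2, 3, 5)
  pred <- c(1.1, 1.9, 3.4, 4.6)
  expect_equal(fitMetrics(obs, 2 * pred + 3)$r2, fitMetrics(obs, pred)$r2)
  expect_false(fitMetrics(obs, 2 * pred + 3)$rmse ==
                 fitMetrics(obs, pred)$rmse)

  expect_error(fitMetrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(fitMetrics(1:2, 1:2), "at least 3")
  expect_error(fitMetrics(1:4, 1:3), "equal length")
})

test_that("looCV equals a hand-written fold-by-fold loop", {
  set.seed(25)
  X <- matrix(stats::runif(12 * 3), 12, 3)
  y <- stats::runif(12)
  grid <- gridSpec(3, 3)
  cfg <- trainConfig(epochs = 15, seed = 55)
  cv <- looCV(X, y, grid, cfg)
  ref <- numeric(12)
  for (k in 1:12) {
    cfgK <- cfg
    cfgK@seed <- fdQSAR:::.deriveSeed(55, k)
    mK <- trainCPANN(X[-k, ], y[-k], grid, cfgK)
    ref[k] <- unname(predict(mK, X[k, ]))
  }
  expect_identical(cv$predictions$predicted, ref)
  fmRef <- fitMetrics(y, ref)
  expect_equal(cv$q2cv, fmRef$r2)
  expect_equal(cv$rmsecv, fmRef$rmse)
  expect_error(looCV(X[1:2, ], y[1:2], grid, cfg), "at least 3")
})

test_that("held-out Q2 does not beat training R2 on noisy data (10 seeds)", {
  ok <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    X <- matrix(stats::runif(20 * 2), 20, 2)
    y <- pmin(1, pmax(0, 0.5 * X[, 1] + 0.25 + stats::rnorm(20, 0, 0.15)))
    grid <- gridSpec(4, 4)
    cfg <- trainConfig(epochs = 25, seed = s)
    m <- trainCPANN(X, y, grid, cfg)
    r2 <- fitMetrics(y, predict(m, X))$r2
    q2 <- looCV(X, y, grid, cfg)$q2cv
    if (q2 <= r2 + 1e-9) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("duplicated objects make held-out prediction near-trivial", {
  set.seed(26)
  X1 <- matrix(stats::runif(10 * 2), 10, 2)
  y1 <- X1[, 1]
  X <- rbind(X1, X1)
  y <- c(y1, y1)
  grid <- gridSpec(6, 6)
  cfg <- trainConfig(epochs = 60, radiusEnd = 0, seed = 9)
  m <- trainCPANN(X, y, grid, cfg)
  r2 <- fitMetrics(y, predict(m, X))$r2
  q2 <- looCV(X, y, grid, cfg)$q2cv
  expect_gt(q2, r2 - 0.1)
})

test_that("a noiseless monotone response is learnt to r2 >= 0.95", {
  set.seed(27)
  x1 <- stats::runif(100)
  X <- cbind(a = x1, b = sqrt(x1))  # low-dimensional descriptor manifold
  y <- x1^2  # monotone in column "a", noiseless
  m <- trainCPANN(X, y, gridSpec(10, 10), trainConfig(epochs = 100, seed = 13))
  expect_gte(fitMetrics(y, predict(m, X))$r2, 0.95)
})

test_that("denormalized predictions return to original target units", {
  set.seed(28)
  X <- matrix(stats::runif(40 * 2), 40, 2)
  raw <- 4000 + 3000 * X[, 1]
  ny <- normalizeColumns(matrix(raw, ncol = 1, dimnames = list(NULL, "b")))
  m <- trainCPANN(X, ny$data[, 1], gridSpec(5, 5),
                  trainConfig(epochs = 50, seed = 4), targetScale = ny$scale)
  pred <- predict(m, X, denormalize = TRUE)
  expect_true(all(pred > 3500 & pred < 7500))
  expect_gte(fitMetrics(raw, pred[, 1])$r2, 0.9)
})
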