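# Independent reference implementations used as oracles in the tests.
# These deliberately share no code with the package internals beyond the
# published update equations.

# exhaustive winner search: plain double loop, smallest row-major index wins
naiveWinner <- function(weights, x) {
  best <- 1L
  bestd <- Inf
  for (n in seq_len(nrow(weights))) {
    d2 <- 0
    for (k in seq_along(x)) d2 <- d2 + (x[k] - weights[n, k])^2
    if (d2 < bestd) {
      bestd <- d2
      best <- n
    }
  }
  list(index = best, distance = sqrt(bestd))
}

# naive R reimplementation of sequential Kohonen/CPANN training, driven by
# the same initial weights and presentation orders as the compiled core
naiveTrain <- function(X, Y, W0x, W0y, orders, etas, radii, nx, ny) {
  Wx <- W0x
  Wy <- W0y
  coords <- cbind(rep(seq_len(nx), each = ny), rep(seq_len(ny), nx))
  for (e in seq_len(nrow(orders))) {
    for (o in orders[e, ]) {
      win <- naiveWinner(Wx, X[o, ])$index
      dt <- pmax(abs(coords[, 1] - coords[win, 1]),
                 abs(coords[, 2] - coords[win, 2]))
      a <- pmax(0, 1 - dt / (radii[e] + 1))
      f <- etas[e] * a
      for (n in which(f > 0)) {
        Wx[n, ] <- Wx[n, ] + f[n] * (X[o, ] - Wx[n, ])
        if (ncol(Y) > 0) Wy[n, ] <- Wy[n, ] + f[n] * (Y[o, ] - Wy[n, ])
      }
    }
  }
  list(Wx = Wx, Wy = Wy)
}

# two well-separated Gaussian blobs in [0, 1]^d, labels attached
makeTwoClusters <- function(nPer = 15, d = 3, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::rnorm(nPer * d, 0.2, 0.02), nPer, d)
  b <- matrix(stats::rnorm(nPer * d, 0.8, 0.02), nPer, d)
  x <- rbind(a, b)
  x[x < 0] <- 0
  x[x > 1] <- 1
  rownames(x) <- paste0("o", seq_len(2 * nPer))
  list(x = x, label = rep(1:2, each = nPer))
}

randomModel <- function(nx, ny, nf, seed) {
  set.seed(seed)
  new("SOMModel", grid = gridSpec(nx, ny),
      weights = matrix(stats::runif(nx * ny * nf), nx * ny, nf),
      featureNames = paste0("f", seq_len(nf)),
      config = trainConfig(seed = seed), trained = TRUE)
}
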