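# Synthetic data generator: shapes, determinism, calibrated structure.

test_that("default configuration yields the study data shapes", {
  ds <- generateDataset(synthConfig())
  expect_equal(dim(descriptors(ds)), c(169, 27))
  expect_equal(dim(bindings(ds)), c(169, 200))
  expect_equal(rownames(descriptors(ds))[1], "FD1")
  expect_true(all(c("QPpolrz", "TD", "sp3_atoms", "aromatic_atoms",
                    "stereo_centers") %in% colnames(descriptors(ds))))
  lat <- trueLatents(ds)
  expect_length(lat$size, 169)
  expect_length(lat$proteinCluster, 200)
  expect_equal(sort(unique(lat$proteinCluster)), 1:5)
})

test_that("the full-scale option reproduces the 169 x 1117 panel", {
  cfg <- synthConfig(nProteins = 1117, seed = 2)
  ds <- generateDataset(cfg)
  expect_equal(dim(bindings(ds)), c(169, 1117))
})

test_that("generation is a deterministic function of config and seed", {
  cfg <- synthConfig(nCompounds = 30, nProteins = 20, seed = 9)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(descriptors(d1), descriptors(d2))
  expect_identical(bindings(d1), bindings(d2))
  d3 <- generateDataset(synthConfig(nCompounds = 30, nProteins = 20, seed = 10))
  expect_false(identical(descriptors(d1), descriptors(d3)))
  # component generators compose to the same dataset
  gd <- generateDescriptors(cfg)
  expect_identical(gd$X, descriptors(d1))
  B <- suppressWarnings(generateBindings(cfg, gd$latents))
  expect_identical(unname(B[, 1]), unname(bindings(d1)[, 1]))
})

test_that("zero noise makes the signal exactly affine in the latents", {
  cfg <- synthConfig(nCompounds = 50, nProteins = 30, noiseSd = 0, seed = 4)
  gd <- generateDescriptors(cfg)
  s <- gd$latents$size
  # continuous size-block columns are exact affine functions of the latent
  for (col in c("QPpolrz", "total_surface_area", "Mol_weight"))
    expect_equal(abs(pearsonCC(gd$X[, col], s)), 1.0, tolerance = 1e-12)
  # count columns only lose rounding precision
  expect_gt(pearsonCC(gd$X[, "non_H_atoms"], s), 0.999)
  B <- generateBindings(cfg, gd$latents)
  for (p in c(1, 15, 30))
    expect_equal(abs(pearsonCC(B[, p], s)), 1.0, tolerance = 1e-12)
  expect_equal(pearsonCC(rowMeans(B), s), 1.0, tolerance = 1e-12)
})

test_that("realized correlations approach the configured targets", {
  cfg <- synthConfig(nCompounds = 2000, seed = 66)
  ds <- generateDataset(cfg)
  X <- descriptors(ds)
  ccAr <- pearsonCC(X[, "aromatic_atoms"], X[, "sp3_atoms"])
  expect_lt(abs(ccAr - cfg$aromaticCC), 0.07)
  avg <- averageBscores(bindings(ds))
  expect_gte(pearsonCC(avg, X[, "QPpolrz"]), 0.85)
  # size block is positively inter-correlated
  sizeCols <- c("QPpolrz", "TD", "total_surface_area", "Mol_weight",
                "non_H_atoms", "rotatable_bonds")
  cm <- correlationMatrix(X[, sizeCols])
  expect_true(all(cm[upper.tri(cm)] > 0.8))
})

test_that("ground truth is recoverable by a CPANN on the descriptors", {
  # suppress the (expected) report of rare scores beyond the plausible range
  ds <- suppressWarnings(generateDataset(synthConfig(seed = 12)))
  X <- normalizeColumns(descriptors(ds))$data
  avg <- averageBscores(bindings(ds))
  y <- normalizeColumns(matrix(avg, ncol = 1))$data[, 1]
  m <- trainCPANN(X, y, gridSpec(12, 12), trainConfig(epochs = 60, seed = 12))
  pred <- predict(m, X)[, 1]
  expect_gte(fitMetrics(y, pred)$r2, 0.9)
  expect_gte(pearsonCC(pred, trueLatents(ds)$size), 0.8)
})

test_that("count descriptors are non-negative integers", {
  ds <- generateDescriptors(synthConfig(nCompounds = 100, seed = 3))
  for (col in c("TD", "non_H_atoms", "rotatable_bonds", "aromatic_atoms",
                "sp3_atoms", "stereo_centers", "H_acceptors", "amides"))
    expect_true(all(ds$X[, col] >= 0 & ds$X[, col] == round(ds$X[, col])))
})

test_that("fixture export writes TSVs plus a checksum manifest", {
  dir <- withr::local_tempdir()
  cfg <- synthConfig(nCompounds = 10, nProteins = 8, seed = 5)
  ds <- generateDataset(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "descriptors.tsv")))
  expect_true(file.exists(file.path(dir, "bindings.tsv")))
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^seed\t5", manifest)))
  expect_true(any(grepl("md5:descriptors.tsv", manifest)))
  back <- readMatrix(file.path(dir, "descriptors.tsv"))
  expect_equal(back, descriptors(ds), tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(nCompounds = 1), ">= 2")
  expect_error(synthConfig(noiseSd = -0.1), "noiseSd")
  expect_error(synthConfig(bscoreGain = 0), "positive")
  expect_error(synthConfig(aromaticCC = 0), "magnitude")
  cfg <- synthConfig(nCompounds = 20, seed = 1)
  expect_error(generateBindings(cfg, list(size = stats::runif(5))),
               "compound count")
  expect_error(generateDescriptors(list(nCompounds = 5)), "synthConfig")
})
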