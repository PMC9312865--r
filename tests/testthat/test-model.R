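test_that("GraphConv output is bounded with self-only sentinel slots", {
  g <- featurizeAtoms(mkStruct(rep("C", 3), cbind(0:2 * 1.5, 0, 0),
                               bonds = rbind(c(1, 2), c(2, 3))))
  W0 <- matrix(0, 75, 75)
  out0 <- graphConvLayer(g@features, g@neighbors, W0, W0, numeric(75))
  expect_true(all(out0 == 0))

  withr::with_seed(5, {
    Ws <- matrix(rnorm(75 * 75, sd = 0.2), 75, 75)
    Wn <- matrix(rnorm(75 * 75, sd = 0.2), 75, 75)
    b <- rnorm(75, sd = 0.1)
  })
  out <- graphConvLayer(g@features, g@neighbors, Ws, Wn, b)
  expect_true(all(out > -1 & out < 1))

  lone <- featurizeAtoms(mkStruct("C", c(0, 0, 0)))
  outL <- graphConvLayer(lone@features, lone@neighbors, Ws, Wn, b)
  for (s in 2:10) expect_equal(outL[, , s], outL[, , 1])

  expect_error(graphConvLayer(g@features[, 1:10], g@neighbors, Ws, Wn, b),
               "dimension")
})

test_that("normalize-then-pool equals a brute-force per-entry maximum", {
  withr::with_seed(11, arr <- array(rnorm(4 * 75 * 10), c(4, 75, 10)))
  pooled <- poolAndNormalize(arr, mode = "eval",
                             runningMean = numeric(75),
                             runningVar = rep(1, 75), eps = 0)
  ref <- apply(arr, c(1, 2), max)
  expect_equal(pooled, ref, tolerance = 1e-12)

  # constant across the neighbor axis: pooling is the identity on that axis
  cst <- array(rep(rnorm(4 * 75), 10), c(4, 75, 10))
  pooledC <- poolAndNormalize(cst, mode = "eval",
                              runningMean = numeric(75),
                              runningVar = rep(1, 75), eps = 0)
  expect_equal(pooledC, cst[, , 1], tolerance = 1e-12)

  # eval mode is deterministic
  expect_identical(pooled,
                   poolAndNormalize(arr, mode = "eval",
                                    runningMean = numeric(75),
                                    runningVar = rep(1, 75), eps = 0))
})

test_that("GraphGather is a permutation-invariant tanh of member sums", {
  withr::with_seed(7, X <- matrix(rnorm(6 * 75), 6, 75))
  mem <- c(1L, 1L, 1L, 2L, 2L, 2L)
  gth <- graphGather(X, mem)
  expect_equal(gth[1, ], tanh(colSums(X[1:3, ])))
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  expect_equal(graphGather(X[perm, ], mem), gth)
  # disjoint graphs gather like singletons
  expect_equal(graphGather(X[4:6, , drop = FALSE], rep(1L, 3)),
               gth[2, , drop = FALSE], ignore_attr = TRUE)
  one <- graphGather(X[1, , drop = FALSE], 1L)
  expect_equal(one[1, ], tanh(X[1, ]))
})

test_that("the model variable is a non-negative deterministic reduction", {
  withr::with_seed(9, {
    W1 <- matrix(rnorm(75 * 8), 75, 8); b1 <- rnorm(8)
    W2 <- matrix(rnorm(8), 8, 1); b2 <- 0.3
    v <- rnorm(75)
  })
  expect_identical(modelVariable(v, matrix(0, 75, 8), numeric(8),
                                 matrix(0, 8, 1), 0), 0)
  m1 <- modelVariable(v, W1, b1, W2, b2)
  expect_gte(m1, 0)
  expect_identical(m1, modelVariable(v, W1, b1, W2, b2))
})

test_that("a fresh model carries the thermodynamic initialization exactly", {
  m <- pgnnModel(pgnnConfig(seed = 21))
  hw <- m@weights$headW
  expect_identical(unname(hw[1:16]), unname(c(physicsInitPattern())))
  expect_identical(unname(hw[17]), 0.5)
  expect_identical(m@weights$headB, 0)
  tab <- headCoefficients(m)
  termRows <- tab$parameter %in% c("VDWAALS", "EELEC", "ESURF", "EGB",
                                   "1-4-eel")
  expect_true(all(tab$complex[termRows] == 1))
  expect_true(all(tab$receptor[termRows] == -1))
  expect_true(all(tab$ligand[termRows] == -1))
  expect_identical(tab$value[tab$parameter == "Entropy"], -1)
  expect_identical(tab$value[tab$parameter == "Model variable"], 0.5)

  # identical seeds give bitwise-identical weight states
  m2 <- pgnnModel(pgnnConfig(seed = 21))
  expect_identical(m@weights, m2@weights)

  # coefficient table round-trips through CSV
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  expect_equal(utils::read.csv(csv, check.names = FALSE), tab,
               ignore_attr = TRUE)
})

test_that("the initialized forward pass is the thermodynamic dot product", {
  m <- pgnnModel(pgnnConfig(seed = 2))
  g <- featurizeAtoms(mkStruct(rep("C", 4), cbind(0:3 * 1.5, 0, 0),
                               bonds = cbind(1:3, 2:4)))
  P <- withr::with_seed(8, rnorm(16))
  names(P) <- physicsFeatureNames()
  expect_equal(predictDdg(m, g, P), sum(physicsInitPattern() * P),
               tolerance = 1e-9)
  # linear head: +delta on the entropy entry shifts the prediction by -delta
  P2 <- P; P2[["entropy"]] <- P2[["entropy"]] + 0.75
  expect_equal(predictDdg(m, g, P2), predictDdg(m, g, P) - 0.75,
               tolerance = 1e-9)
  expect_error(predictDdg(m, g, P[1:10]), "16")
})

test_that("batched eval forwards equal stacked singleton forwards", {
  ds <- tinyDataset(n = 5, seed = 23, s = 1)
  fit <- trainPGNN(ds, tinyConfig(epochs = 2, seed = 3))
  batchPred <- predictDdg(fit, ds)
  singles <- vapply(ds, function(it) predictDdg(fit, it$graph, it$P),
                    numeric(1))
  expect_equal(batchPred, singles, tolerance = 1e-5)
})

test_that("training is reproducible and logs every epoch", {
  ds <- tinyDataset(n = 6, seed = 29, s = 1, noise = 0.1)
  cfg <- tinyConfig(epochs = 4, seed = 17)
  f1 <- trainPGNN(ds, cfg, valData = ds[1:2])
  f2 <- trainPGNN(ds, cfg, valData = ds[1:2])
  expect_identical(f1@trainingLog, f2@trainingLog)
  expect_identical(f1@weights, f2@weights)
  expect_equal(nrow(f1@trainingLog), 4L)
  expect_false(any(is.na(f1@trainingLog$valLoss)))
  expect_error(trainPGNN(list(), cfg), "empty")
})

test_that("prediction is invariant under atom reordering of the input", {
  st <- makeHostGuest(fixtureSpec(seed = 31, atomsPerHost = c(12L, 12L),
                                  atomsPerGuest = c(4L, 4L)), 1)@complexStructure
  n <- nAtoms(st)
  perm <- withr::with_seed(4, sample.int(n))
  stP <- st
  stP@atoms <- st@atoms[perm, , drop = FALSE]
  rownames(stP@atoms) <- NULL
  inv <- integer(n); inv[perm] <- seq_len(n)
  stP@bonds <- matrix(as.integer(inv[st@bonds]), ncol = 2)
  m <- pgnnModel(pgnnConfig(seed = 6))
  # nonzero M path so the graph actually influences the output
  m@weights$W2 <- matrix(0.1, m@config$headHidden, 1)
  m@weights$b2 <- 0.5
  P <- withr::with_seed(5, rnorm(16))
  pA <- predictDdg(m, featurizeAtoms(st), P)
  pB <- predictDdg(m, featurizeAtoms(stP), P)
  expect_equal(pA, pB, tolerance = 1e-9)
})

test_that("checkpoints round-trip through JSON exactly", {
  ds <- tinyDataset(n = 5, seed = 37, s = 1)
  fit <- trainPGNN(ds, tinyConfig(epochs = 2, seed = 11))
  path <- tempfile(fileext = ".json")
  writeModel(fit, path)
  back <- readModel(path)
  expect_equal(back@weights, fit@weights, tolerance = 1e-12)
  expect_equal(predictDdg(back, ds), predictDdg(fit, ds), tolerance = 1e-12)
  expect_equal(back@config, fit@config)
})
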