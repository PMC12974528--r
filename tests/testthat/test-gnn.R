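pg <- asNamespace("pocketgraph")

test_that("encoder output has one hidden vector per node and per edge", {
  cx <- smallBenchmark()[[1]]
  g <- assembleGraph(cx@protein, list(cx@trueLigand))
  model <- initModel(modelConfig(2, 16, seed = 3))
  enc <- encodeGraph(model, g)
  expect_equal(dim(enc$H), c(nrow(g@nodeFeatures), 16))
  expect_equal(dim(enc$E), c(2 * nrow(g@edges), 16))
  expect_true(all(is.finite(enc$H)))
  expect_length(enc$hPVirt, 16)
})

test_that("node outputs are permutation-equivariant, hub scores invariant", {
  # permute the node order of a small graph manually and compare
  cx <- smallBenchmark()[[2]]
  g <- assembleGraph(cx@protein, list(cx@trueLigand))
  model <- initModel(modelConfig(2, 16, seed = 3))
  n <- nrow(g@nodeFeatures)
  perm <- withr::with_seed(4, sample(n))
  gp <- g
  inv <- order(perm)
  gp@nodeFeatures <- g@nodeFeatures[perm, , drop = FALSE]
  gp@nodeMeta <- g@nodeMeta[perm, , drop = FALSE]
  gp@edges$src <- inv[g@edges$src]
  gp@edges$dst <- inv[g@edges$dst]
  gp@proteinVirtualIndex <- inv[g@proteinVirtualIndex]
  gp@ligandVirtualIndices <- inv[g@ligandVirtualIndices]
  enc <- encodeGraph(model, g)
  encP <- encodeGraph(model, gp)
  expect_equal(encP$H, enc$H[perm, , drop = FALSE], tolerance = 1e-10)
  expect_equal(encP$hPVirt, enc$hPVirt, tolerance = 1e-10)
  s1 <- pairingScore(model, enc$hPVirt, enc$hLVirt[1, ])
  s2 <- pairingScore(model, encP$hPVirt, encP$hLVirt[1, ])
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("pairing score is symmetric and zero-hub gives the bias point", {
  model <- initModel(modelConfig(1, 8, seed = 2))
  h1 <- rnorm(8); h2 <- rnorm(8)
  expect_equal(pairingScore(model, h1, h2), pairingScore(model, h2, h1))
  # zero hub annihilates the product: score independent of the other vector
  expect_equal(pairingScore(model, rep(0, 8), h1),
               pairingScore(model, rep(0, 8), h2))
  expect_error(pairingScore(model, h1, rnorm(5)), "mismatch")
})

test_that("pocket probability lies in (0,1) and respects the sigmoid", {
  model <- initModel(modelConfig(1, 8, seed = 2))
  h <- rnorm(8); hl <- rnorm(8)
  pr <- pocketProbability(model, h, hl)
  expect_gt(pr, 0); expect_lt(pr, 1)
  # zero product vector puts the head at its bias point
  p0 <- pocketProbability(model, rep(0, 8), hl)
  b <- tanh(model@params$bk1) %*% model@params$wk2 + model@params$bk2[1, 1]
  expect_equal(p0, 1 / (1 + exp(-as.numeric(b))), tolerance = 1e-12)
})

test_that("batch of 1 true + k decoys yields k+1 pairing scores", {
  cx <- smallBenchmark()[[1]]
  pr <- predictResidues(tinyTrainedModel(), cx@protein, cx@trueLigand,
                        decoys = cx@decoys[1:3])
  expect_length(pr$pairingScores, 4)
  expect_length(pr$residueProbs, residueCount(cx@protein))
  expect_true(all(pr$residueProbs > 0 & pr$residueProbs < 1))
})

test_that("residue probability is the max of the residue's two node probs", {
  cx <- smallBenchmark()[[1]]
  pr <- predictResidues(tinyTrainedModel(), cx@protein, cx@trueLigand)
  m <- residueCount(cx@protein)
  bb <- pr$nodeProbs[seq(1, 2 * m, 2)]
  sc <- pr$nodeProbs[seq(2, 2 * m, 2)]
  expect_equal(pr$residueProbs, pmax(bb, sc))
})

test_that("training reduces the loss components and is seed-reproducible", {
  h <- tinyTrainedModel()@history
  # compare like with like: the Dice gate may open mid-run and add a term
  # to L_total, so the smoke check is on the pairing and BCE components
  expect_lt(h$L_pairing[nrow(h)], h$L_pairing[1])
  expect_lt(h$L_bce[nrow(h)], h$L_bce[1])
  again <- trainResidueModel(smallBenchmark(), modelConfig(2, 16, seed = 5),
                             epochs = 4, nDecoys = 3, seed = 9)
  expect_identical(again@history$L_total, h$L_total)
})

test_that("changing the query ligand changes the residue ranking", {
  model <- tinyTrainedModel()
  cx <- smallBenchmark()[[1]]
  ligA <- makeLigand(7, elementBias = c(C = 0.3, O = 0.45, N = 0.25),
                     seed = 41, id = "qa")
  ligB <- makeLigand(7, elementBias = c(C = 0.9, S = 0.05, F = 0.05),
                     seed = 42, id = "qb")
  pA <- predictResidues(model, cx@protein, ligA)$residueProbs
  pB <- predictResidues(model, cx@protein, ligB)$residueProbs
  expect_false(isTRUE(all.equal(pA, pB)))
})

test_that("checkpoints round-trip through JSON exactly", {
  model <- tinyTrainedModel()
  f <- tempfile(fileext = ".json")
  saveCheckpoint(model, f)
  back <- loadCheckpoint(f)
  expect_identical(back@mode, model@mode)
  # JSON prints doubles at 15 significant digits
  expect_equal(back@params, model@params, tolerance = 1e-12)
  expect_equal(back@config$hiddenDim, model@config$hiddenDim)
  cx <- smallBenchmark()[[1]]
  expect_equal(predictResidues(back, cx@protein, cx@trueLigand)$residueProbs,
               predictResidues(model, cx@protein, cx@trueLigand)$residueProbs,
               tolerance = 1e-12)
})

test_that("decoy request larger than the pool falls back with a warning", {
  cxs <- smallBenchmark()[1:2]
  w <- capture_warnings(
    trainResidueModel(cxs, modelConfig(1, 8, seed = 2), epochs = 1,
                      nDecoys = 50, seed = 3))
  expect_true(length(w) >= 1)
  expect_match(w, "pool smaller", all = TRUE)
})
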