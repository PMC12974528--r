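# Desk-scale trainers for the residue-level and coordinate-level (probe)
# modes. All randomness (decoy choice, shuffling, initialization) sits
# behind explicit seeds; the same seed reproduces the loss curve exactly.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Dice loss on the tape from pocket logits and constant labels.
buildDice <- function(tape, logits, y, smooth = 1.0) {
  p <- adSigmoid(tape, logits)
  py <- adMul(tape, p, adLeaf(tape, matrix(y, ncol = 1)))
  num <- adConstPlus(tape, adScale(tape, adSum(tape, py), 2), smooth)
  den <- adConstPlus(tape, adSum(tape, p), sum(y) + smooth)
  adConstPlus(tape, adScale(tape, adSDiv(tape, num, den), -1), 1)
}

# One residue-mode training example: forward, loss, gradients.
residueStep <- function(params, gt, nodeLabels, posWeight, config, gateOpen) {
  tape <- adTape()
  enc <- buildEncoder(tape, params, gt, config)
  scores <- buildPairingHead(tape, enc, gt)
  lPair <- adSAdd(tape, adLogSumExp(tape, scores),
                  adScale(tape, adPick(tape, scores, 1L), -1))
  logits <- buildPocketHead(tape, enc, gt, 1L)
  lBce <- adBceLogits(tape, logits, nodeLabels, posWeight)
  lDiceId <- buildDice(tape, logits, nodeLabels)
  lPocket <- if (gateOpen) adSAdd(tape, lBce, lDiceId) else lBce
  total <- adSAdd(tape, lPair, lPocket)
  pidIds <- unlist(enc$pid)
  grads <- adBackward(tape, total, as.list(pidIds))
  names(grads) <- names(enc$pid)
  nodeProbs <- 1 / (1 + exp(-as.numeric(adValue(tape, logits))))
  list(grads = grads,
       lPairing = adValue(tape, lPair)[1], lBce = adValue(tape, lBce)[1],
       lDice = adValue(tape, lDiceId)[1], lTotal = adValue(tape, total)[1],
       nodeProbs = nodeProbs)
}

#' Train the residue-level model on a set of complexes
#'
#' Optimizes L_total = L_pairing + L_pocket with Adam. L_pairing is the
#' InfoNCE over the true ligand and `nDecoys` decoys sampled once per
#' complex; L_pocket is the weighted BCE (positive weight = #neg/#pos capped
#' at 100) plus the Dice term once the running F1 (EMA, decay 0.9) has
#' exceeded 0.2 (the gate latches open).
#'
#' @param complexes list of \linkS4class{SyntheticComplex} (or any objects
#'   with protein, trueLigand, decoys slots).
#' @param config from [modelConfig()].
#' @param epochs training epochs (default 30).
#' @param nDecoys decoys per complex used in the pairing loss (default 5;
#'   falls back to the available pool size with a warning).
#' @param lr Adam learning rate.
#' @param batchSize complexes per gradient step (default 4).
#' @param seed seed for decoy sampling and shuffling.
#' @param lossCsv optional path; when set, the per-epoch loss history is
#'   streamed to CSV.
#' @return A trained \linkS4class{PocketModel} with its loss history.
#' @export
trainResidueModel <- function(complexes, config = modelConfig(), epochs = 30,
                              nDecoys = 5, lr = 1e-3, batchSize = 4,
                              seed = 1L, lossCsv = NULL) {
  stopifnot(length(complexes) >= 1)
  model <- initModel(config, mode = "residue")
  params <- model@params
  prep <- withSeed(seed, lapply(complexes, function(cx) {
    k <- nDecoys
    if (length(cx@decoys) < k) {
      warning("decoy pool smaller than requested; using ", length(cx@decoys))
      k <- length(cx@decoys)
    }
    decoys <- cx@decoys[sample.int(length(cx@decoys), k)]
    graph <- assembleGraph(cx@protein, c(list(cx@trueLigand), decoys))
    y <- makeLabels(cx@protein, cx@trueLigand)@y
    nodeLabels <- rep(y, each = 2)
    pos <- sum(nodeLabels); neg <- length(nodeLabels) - pos
    list(gt = graphTensors(graph, config), nodeLabels = nodeLabels,
         posWeight = min(if (pos > 0) neg / pos else 1, 100))
  }))
  state <- adamInit(params)
  runningF1 <- 0; gateOpen <- FALSE
  history <- vector("list", epochs)
  orders <- withSeed(seed + 1L, lapply(seq_len(epochs), function(e)
    sample.int(length(prep))))
  for (epoch in seq_len(epochs)) {
    ord <- orders[[epoch]]
    ep <- c(L_pairing = 0, L_bce = 0, L_dice = 0, L_total = 0)
    batches <- split(ord, ceiling(seq_along(ord) / batchSize))
    for (batch in batches) {
      acc <- NULL
      f1s <- numeric(length(batch))
      for (bi in seq_along(batch)) {
        px <- prep[[batch[bi]]]
        st <- residueStep(params, px$gt, px$nodeLabels, px$posWeight,
                          config, gateOpen)
        acc <- if (is.null(acc)) st$grads
               else Map(`+`, acc, st$grads)
        f1s[bi] <- f1Score(st$nodeProbs, px$nodeLabels)
        ep <- ep + c(st$lPairing, st$lBce, st$lDice, st$lTotal)
      }
      acc <- lapply(acc, function(g) g / length(batch))
      upd <- adamStep(params, acc, state, lr = lr)
      params <- upd$params; state <- upd$state
      runningF1 <- 0.9 * runningF1 + 0.1 * mean(f1s)
      if (runningF1 > 0.2) gateOpen <- TRUE
    }
    ep <- ep / length(ord)
    history[[epoch]] <- data.frame(epoch = epoch, L_pairing = ep[1],
                                   L_bce = ep[2], L_dice = ep[3],
                                   L_pocket = ep[4] - ep[1], L_total = ep[4],
                                   running_f1 = runningF1, gate = gateOpen)
  }
  history <- do.call(rbind, history)
  rownames(history) <- NULL
  if (!is.null(lossCsv)) utils::write.csv(history, lossCsv, row.names = FALSE)
  model@params <- params
  model@history <- history
  model
}

# One probe-mode contrastive group: the positive probe graph first, then
# decoy graphs (far probes and wrong-ligand probes); InfoNCE over the probe
# scores.
probeGroupStep <- function(params, gts, config) {
  tape <- adTape()
  pid <- lapply(params, function(v) adLeaf(tape, v))
  scoreIds <- lapply(gts, function(gt) {
    enc <- buildEncoder(tape, params, gt, config, pid = pid)
    h <- adRows(tape, enc$H, probeNodeIndex(gt))
    adAddBias(tape, adMatmul(tape, h, pid$wq), pid$bq)
  })
  scores <- adRbind(tape, scoreIds)
  loss <- adSAdd(tape, adLogSumExp(tape, scores),
                 adScale(tape, adPick(tape, scores, 1L), -1))
  grads <- adBackward(tape, loss, as.list(unlist(pid)))
  names(grads) <- names(pid)
  list(grads = grads, loss = adValue(tape, loss)[1],
       scores = as.numeric(adValue(tape, scores)))
}

probeNodeIndex <- function(gt) gt$pvi

#' Train the coordinate-level (probe) model
#'
#' For each complex, solvent-accessible-surface probes are generated and
#' labeled against the true ligand center (< 4.0 A positive). Each training
#' group pairs one positive probe graph with `nFar` far-probe decoys and
#' `nWrong` wrong-ligand decoys (the positive probe paired with a randomly
#' chosen decoy ligand), optimized with InfoNCE. Complexes without a
#' positive probe are skipped.
#'
#' @param complexes list of \linkS4class{SyntheticComplex}.
#' @param config from [modelConfig()].
#' @param epochs epochs (default 10).
#' @param nFar,nWrong decoys per group (default 2 each).
#' @param latticeCount Shrake-Rupley points per atom (default 24 for speed).
#' @param cutoff probe local-graph residue cutoff, Angstrom (default 10).
#' @param lr Adam learning rate.
#' @param seed seed for probe/decoy sampling and shuffling.
#' @return A trained \linkS4class{PocketModel} in probe mode.
#' @export
trainProbeModel <- function(complexes, config = modelConfig(), epochs = 10,
                            nFar = 2, nWrong = 2, latticeCount = 24,
                            cutoff = 10, lr = 1e-3, seed = 1L) {
  model <- initModel(config, mode = "probe")
  params <- model@params
  groups <- withSeed(seed, {
    out <- list()
    for (cx in complexes) {
      g <- makeProbeGroup(cx, nFar, nWrong, latticeCount, cutoff, config)
      if (!is.null(g)) out[[length(out) + 1L]] <- g
    }
    out
  })
  if (!length(groups)) stop("no complex produced a positive probe")
  state <- adamInit(params)
  hist <- numeric(epochs)
  orders <- withSeed(seed + 1L, lapply(seq_len(epochs), function(e)
    sample.int(length(groups))))
  for (epoch in seq_len(epochs)) {
    tot <- 0
    for (gi in orders[[epoch]]) {
      st <- probeGroupStep(params, groups[[gi]], config)
      upd <- adamStep(params, st$grads, state, lr = lr)
      params <- upd$params; state <- upd$state
      tot <- tot + st$loss
    }
    hist[epoch] <- tot / length(groups)
  }
  model@params <- params
  model@history <- data.frame(epoch = seq_len(epochs), L_probe = hist)
  model
}

# Build the tensors of one contrastive probe group for a complex, or NULL
# when no positive probe exists.
makeProbeGroup <- function(cx, nFar, nWrong, latticeCount, cutoff, config) {
  probes <- shrakeRupley(cx@protein@atoms, count = latticeCount)
  center <- colMeans(ligandCoords(cx@trueLigand))
  probes <- labelProbes(probes, center)
  posIdx <- which(probes@label == 1L)
  negIdx <- which(probes@label == 0L)
  if (!length(posIdx) || length(negIdx) < nFar) return(NULL)
  pos <- posIdx[sample.int(length(posIdx), 1)]
  far <- negIdx[sample.int(length(negIdx), min(nFar, length(negIdx)))]
  wrongLigs <- cx@decoys[sample.int(length(cx@decoys), min(nWrong, length(cx@decoys)))]
  ctx <- probeGraphContext(cx@protein, cutoff)
  graphs <- c(
    list(buildProbeGraph(probes@coords[pos, ], cx@protein, cx@trueLigand,
                         cutoff = cutoff, context = ctx)),
    lapply(far, function(i)
      buildProbeGraph(probes@coords[i, ], cx@protein, cx@trueLigand,
                      cutoff = cutoff, context = ctx)),
    lapply(wrongLigs, function(lig)
      buildProbeGraph(probes@coords[pos, ], cx@protein, lig,
                      cutoff = cutoff, context = ctx))
  )
  lapply(graphs, graphTensors, config = config)
}
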