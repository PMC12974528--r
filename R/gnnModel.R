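# Message-passing network over the unified graph.
#
# Layer scheme (node and edge embeddings updated jointly):
#   e'_ij = LN( e_ij + tanh(W_e [h_i, h_j, e_ij] + b_e) )
#   m_i   = agg_{j in N(i)} tanh(W_m [h_j, e'_ji] + b_m)
#   h'_i  = LN( h_i + tanh(W_h [h_i, m_i] + b_h) )
# Undirected edges are expanded into both directed orientations, each with
# its own edge embedding. Heads:
#   Score_pairing(k) = MLP_pair(h_PVirt (*) h_LVirt(k))
#   P(pocket_i)      = sigmoid(MLP_pocket(h_i (*) h_LTrue))
#   Score_probe      = linear(h_probe)           (coordinate-level mode)

#' Model configuration
#'
#' @param numLayers number of message-passing layers. The published
#'   architecture uses 16; the package default is a desk-scale 4.
#' @param hiddenDim hidden width (published 128; default 64).
#' @param dScale distances are divided by this (Angstrom) before entering the
#'   network (default 10).
#' @param aggregation "sum" (default) or "mean" message aggregation.
#' @param residueReduce "max" (default) or "mean" to combine a residue's BB
#'   and SC node probabilities.
#' @param seed seed for parameter initialization.
#' @return list of class settings used by [initModel()].
#' @export
modelConfig <- function(numLayers = 4L, hiddenDim = 64L, dScale = 10,
                        aggregation = c("sum", "mean"),
                        residueReduce = c("max", "mean"), seed = 1L) {
  stopifnot(numLayers >= 1, hiddenDim >= 1)
  list(numLayers = as.integer(numLayers), hiddenDim = as.integer(hiddenDim),
       dScale = dScale, aggregation = match.arg(aggregation),
       residueReduce = match.arg(residueReduce), seed = as.integer(seed),
       inputDim = 34L, edgeDim = 5L)
}

glorot <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)

#' Initialize an untrained model
#'
#' @param config from [modelConfig()].
#' @param mode "residue" (pairing + pocket heads) or "probe" (probe scoring
#'   head).
#' @return A \linkS4class{PocketModel}.
#' @export
initModel <- function(config = modelConfig(), mode = c("residue", "probe")) {
  mode <- match.arg(mode)
  d <- config$hiddenDim
  withSeed(config$seed, {
    p <- list(Wn = glorot(config$inputDim, d), bn = matrix(0, 1, d),
              We = glorot(config$edgeDim, d), be = matrix(0, 1, d))
    for (l in seq_len(config$numLayers)) {
      p[[paste0("We", l)]] <- glorot(3 * d, d)
      p[[paste0("bee", l)]] <- matrix(0, 1, d)
      p[[paste0("Wm", l)]] <- glorot(2 * d, d)
      p[[paste0("bm", l)]] <- matrix(0, 1, d)
      p[[paste0("Wh", l)]] <- glorot(2 * d, d)
      p[[paste0("bh", l)]] <- matrix(0, 1, d)
    }
    p$Wp1 <- glorot(d, d); p$bp1 <- matrix(0, 1, d)
    p$wp2 <- glorot(d, 1); p$bp2 <- matrix(0, 1, 1)
    p$Wk1 <- glorot(d, d); p$bk1 <- matrix(0, 1, d)
    p$wk2 <- glorot(d, 1); p$bk2 <- matrix(0, 1, 1)
    p$wq <- glorot(d, 1); p$bq <- matrix(0, 1, 1)
    new("PocketModel", params = p, config = config,
        vocab = list(aa = AA_VOCAB, element = ELEMENT_VOCAB),
        history = data.frame(), mode = mode)
  })
}

# Precompute the dense tensors of one graph (reused across training epochs).
graphTensors <- function(graph, config) {
  e <- graph@edges
  Xe <- cbind(e$d / config$dScale, e$contact, e$bond, e$pGlobal, e$lGlobal)
  list(X = graph@nodeFeatures,
       Xe2 = rbind(Xe, Xe),
       src2 = c(e$src, e$dst), dst2 = c(e$dst, e$src),
       nNodes = nrow(graph@nodeFeatures),
       m = graph@m,
       protNodes = seq_len(2L * graph@m),
       pvi = graph@proteinVirtualIndex,
       lvis = graph@ligandVirtualIndices)
}

# Build the forward computation on a tape. Returns tape node ids for the
# final node embeddings plus leaf ids of every parameter.
buildEncoder <- function(tape, params, gt, config, pid = NULL) {
  if (is.null(pid)) pid <- lapply(params, function(v) adLeaf(tape, v))
  X <- adLeaf(tape, gt$X)
  Xe <- adLeaf(tape, gt$Xe2)
  H <- adAddBias(tape, adMatmul(tape, X, pid$Wn), pid$bn)
  E <- adAddBias(tape, adMatmul(tape, Xe, pid$We), pid$be)
  nE <- length(gt$src2)
  degInv <- if (config$aggregation == "mean") {
    deg <- tabulate(gt$dst2, nbins = gt$nNodes)
    1 / pmax(deg, 1)
  } else NULL
  for (l in seq_len(config$numLayers)) {
    Hs <- adRows(tape, H, gt$src2)
    Hd <- adRows(tape, H, gt$dst2)
    Eup <- adTanh(tape, adAddBias(tape, adMatmul(
      tape, adCbind(tape, Hs, Hd, E), pid[[paste0("We", l)]]),
      pid[[paste0("bee", l)]]))
    E <- adLayerNorm(tape, adAdd(tape, E, Eup))
    Msg <- adTanh(tape, adAddBias(tape, adMatmul(
      tape, adCbind(tape, Hs, E), pid[[paste0("Wm", l)]]),
      pid[[paste0("bm", l)]]))
    M <- adRowsumBy(tape, Msg, gt$dst2, gt$nNodes)
    if (!is.null(degInv)) M <- adMul(tape, M, adLeaf(tape, matrix(degInv, gt$nNodes, config$hiddenDim)))
    Hup <- adTanh(tape, adAddBias(tape, adMatmul(
      tape, adCbind(tape, H, M), pid[[paste0("Wh", l)]]),
      pid[[paste0("bh", l)]]))
    H <- adLayerNorm(tape, adAdd(tape, H, Hup))
  }
  list(H = H, E = E, pid = pid)
}

# Pairing scores for every ligand hub against the protein hub (tape ids).
buildPairingHead <- function(tape, enc, gt) {
  K <- length(gt$lvis)
  P <- adRows(tape, enc$H, rep(gt$pvi, K))
  L <- adRows(tape, enc$H, gt$lvis)
  Z <- adMul(tape, P, L)
  Hid <- adTanh(tape, adAddBias(tape, adMatmul(tape, Z, enc$pid$Wp1), enc$pid$bp1))
  adAddBias(tape, adMatmul(tape, Hid, enc$pid$wp2), enc$pid$bp2)
}

# Pocket logits for every protein structural node against one ligand hub.
buildPocketHead <- function(tape, enc, gt, ligandIndex = 1L) {
  nP <- length(gt$protNodes)
  Hi <- adRows(tape, enc$H, gt$protNodes)
  Hl <- adRows(tape, enc$H, rep(gt$lvis[ligandIndex], nP))
  Z <- adMul(tape, Hi, Hl)
  Hid <- adTanh(tape, adAddBias(tape, adMatmul(tape, Z, enc$pid$Wk1), enc$pid$bk1))
  adAddBias(tape, adMatmul(tape, Hid, enc$pid$wk2), enc$pid$bk2)
}

#' Encode a unified graph into final node and edge embeddings
#'
#' @param model A \linkS4class{PocketModel}.
#' @param graph A \linkS4class{UnifiedGraph}.
#' @return list with H (nodes x hidden), E (directed edges x hidden), and the
#'   hub embeddings hPVirt and hLVirt (one row per ligand).
#' @export
encodeGraph <- function(model, graph) {
  gt <- graphTensors(graph, model@config)
  tape <- adTape()
  enc <- buildEncoder(tape, model@params, gt, model@config)
  H <- adValue(tape, enc$H)
  list(H = H, E = adValue(tape, enc$E),
       hPVirt = H[gt$pvi, ], hLVirt = H[gt$lvis, , drop = FALSE])
}

#' Pairing score between a protein hub vector and a ligand hub vector
#'
#' The element-wise product of the two hub embeddings through the pairing
#' MLP; symmetric in its two arguments.
#'
#' @param model A \linkS4class{PocketModel}.
#' @param hP,hL equal-length hub embedding vectors.
#' @return scalar score.
#' @export
pairingScore <- function(model, hP, hL) {
  if (length(hP) != length(hL)) stop("hub vector length mismatch")
  p <- model@params
  z <- matrix(hP * hL, 1)
  as.numeric(tanh(z %*% p$Wp1 + matrix(p$bp1, 1)) %*% p$wp2 + p$bp2[1, 1])
}

#' Pocket probability for one protein node against the query ligand hub
#'
#' @param model A \linkS4class{PocketModel}.
#' @param hI protein node embedding vector.
#' @param hL query (true) ligand hub embedding vector.
#' @return probability in (0, 1).
#' @export
pocketProbability <- function(model, hI, hL) {
  if (length(hI) != length(hL)) stop("vector length mismatch")
  p <- model@params
  z <- matrix(hI * hL, 1)
  logit <- as.numeric(tanh(z %*% p$Wk1 + matrix(p$bk1, 1)) %*% p$wk2 + p$bk2[1, 1])
  1 / (1 + exp(-logit))
}

#' Ligand-conditional residue-level prediction
#'
#' Assembles the unified graph for one protein and a query ligand (plus
#' optional decoys), runs the network, and returns per-node pocket
#' probabilities, per-residue probabilities (max or mean of each residue's
#' BB/SC nodes per the model config), and the pairing score of every ligand.
#'
#' @param model A \linkS4class{PocketModel} in residue mode.
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligand query \linkS4class{Ligand}.
#' @param decoys optional list of decoy ligands.
#' @return list(residueProbs, nodeProbs, pairingScores).
#' @export
predictResidues <- function(model, protein, ligand, decoys = list()) {
  graph <- assembleGraph(protein, c(list(ligand), decoys))
  gt <- graphTensors(graph, model@config)
  tape <- adTape()
  enc <- buildEncoder(tape, model@params, gt, model@config)
  scores <- as.numeric(adValue(tape, buildPairingHead(tape, enc, gt)))
  logits <- as.numeric(adValue(tape, buildPocketHead(tape, enc, gt, 1L)))
  nodeProbs <- 1 / (1 + exp(-logits))
  residueProbs <- reduceNodeProbs(nodeProbs, graph@m, model@config$residueReduce)
  list(residueProbs = residueProbs, nodeProbs = nodeProbs,
       pairingScores = scores)
}

reduceNodeProbs <- function(nodeProbs, m, reduce = "max") {
  bb <- nodeProbs[seq(1, 2 * m, by = 2)]
  sc <- nodeProbs[seq(2, 2 * m, by = 2)]
  if (reduce == "max") pmax(bb, sc) else (bb + sc) / 2
}

#' Save a model checkpoint as JSON
#'
#' Self-describing archive: parameters, configuration, vocabularies, loss
#' history and mode, written in full double precision.
#'
#' @param model A \linkS4class{PocketModel}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  jsonlite::write_json(list(
    mode = model@mode, config = model@config, vocab = model@vocab,
    history = model@history,
    params = lapply(model@params, function(m) list(dim = dim(m),
                                                   data = as.numeric(m)))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [saveCheckpoint()]
#'
#' @param path checkpoint path.
#' @return A \linkS4class{PocketModel}.
#' @export
loadCheckpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(x$params, function(p) matrix(p$data, p$dim[1], p$dim[2]))
  cfg <- as.list(x$config)
  cfg$numLayers <- as.integer(cfg$numLayers)
  cfg$hiddenDim <- as.integer(cfg$hiddenDim)
  hist <- if (length(x$history)) as.data.frame(x$history) else data.frame()
  new("PocketModel", params = params, config = cfg,
      vocab = lapply(x$vocab, as.character), history = hist, mode = x$mode)
}
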