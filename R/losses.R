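# Training objective: L_total = L_pairing + L_pocket.
#
# L_pairing is an InfoNCE (softmax cross-entropy) over the pairing scores of
# one true ligand and k decoys. L_pocket is a weighted binary cross-entropy
# over per-node pocket probabilities, plus a soft Dice loss that is gated on
# a running F1 of the binarized predictions exceeding 0.2 (the gate latches
# open once crossed).

#' InfoNCE contrastive loss over one true score and k decoy scores
#'
#' @param scores numeric vector of pairing scores (length k + 1).
#' @param trueIndex 1-based index of the true ligand's score.
#' @return -log softmax(scores)[trueIndex], a non-negative scalar equal to
#'   log(k + 1) when all scores are equal.
#' @export
infonce <- function(scores, trueIndex = 1L) {
  if (trueIndex < 1 || trueIndex > length(scores)) stop("trueIndex out of range")
  logSumExp(scores) - scores[trueIndex]
}

#' Weighted binary cross-entropy
#'
#' Mean of -(w * y * log p + (1 - y) * log(1 - p)) with the weight applied to
#' the positive class; probabilities are clamped to [1e-7, 1 - 1e-7].
#'
#' @param probs numeric probabilities.
#' @param labels binary 0/1 labels, same length.
#' @param posWeight weight on the positive class (default 1).
#' @return scalar loss.
#' @export
weightedBce <- function(probs, labels, posWeight = 1) {
  stopifnot(length(probs) == length(labels))
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  mean(-(posWeight * labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Soft Dice loss
#'
#' 1 - (2 * sum(p * y) + s) / (sum(p) + sum(y) + s) with smoothing s = 1 by
#' default; the smoothing keeps the loss defined (and zero) when both the
#' prediction and the label mass vanish.
#'
#' @param probs numeric probabilities.
#' @param labels binary labels.
#' @param smooth smoothing constant (default 1).
#' @return scalar in [0, 1].
#' @export
diceLoss <- function(probs, labels, smooth = 1.0) {
  stopifnot(length(probs) == length(labels))
  1 - (2 * sum(probs * labels) + smooth) / (sum(probs) + sum(labels) + smooth)
}

#' F1 score of binarized probabilities
#'
#' @param probs probabilities; binarized at `threshold`.
#' @param labels binary labels.
#' @param threshold binarization threshold (default 0.5).
#' @return F1 in [0, 1]; 0 when no positive is predicted or labeled.
#' @export
f1Score <- function(probs, labels, threshold = 0.5) {
  pred <- as.numeric(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Pocket loss with the F1-gated Dice term
#'
#' Returns L_bce alone while the running F1 (an exponential moving average of
#' batch F1 at threshold 0.5, maintained by the trainer) has never exceeded
#' 0.2; once it has, the gate latches open and L_bce + L_dice is returned
#' from then on.
#'
#' @param probs probabilities over protein nodes.
#' @param labels binary node labels.
#' @param runningF1 current EMA of the training F1.
#' @param gateOpen whether the gate has latched open previously.
#' @param posWeight positive-class weight for the BCE term.
#' @param gateThreshold F1 threshold opening the gate (default 0.2).
#' @return list(lPocket, lBce, lDice, gateOpen).
#' @export
pocketLoss <- function(probs, labels, runningF1, gateOpen = FALSE,
                       posWeight = 1, gateThreshold = 0.2) {
  lBce <- weightedBce(probs, labels, posWeight)
  lDice <- diceLoss(probs, labels)
  gateOpen <- gateOpen || (runningF1 > gateThreshold)
  list(lPocket = if (gateOpen) lBce + lDice else lBce,
       lBce = lBce, lDice = lDice, gateOpen = gateOpen)
}

#' Combine the loss terms into a loss report
#'
#' @param lPairing pairing (InfoNCE) loss.
#' @param pocket list returned by [pocketLoss()].
#' @param runningF1 current EMA of training F1.
#' @return list with L_pairing, L_bce, L_dice, L_pocket,
#'   L_total = L_pairing + L_pocket, dice_gate_open and running_f1.
#' @export
lossReport <- function(lPairing, pocket, runningF1) {
  list(L_pairing = lPairing, L_bce = pocket$lBce, L_dice = pocket$lDice,
       L_pocket = pocket$lPocket, L_total = lPairing + pocket$lPocket,
       dice_gate_open = pocket$gateOpen, running_f1 = runningF1)
}
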