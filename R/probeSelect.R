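# Greedy construction of a minimal ligand probe set: iteratively add the
# pool ligand that covers the most still-uncovered true pocket residues
# across a batch of proteins, skipping batches already covered beyond the
# threshold by previously selected probes.

#' Residue set covered by a prediction at a probability threshold
#'
#' @param residueProbs probability vector (0-based residue indexing follows
#'   position; returned indices are 1-based positions).
#' @param threshold probability cutoff (default 0.5, inclusive).
#' @return integer vector of covered residue positions.
#' @export
predictedCover <- function(residueProbs, threshold = 0.5) {
  which(residueProbs >= threshold)
}

#' Recall of true pocket residues
#'
#' @param covered integer set of covered residues.
#' @param trueSet non-empty integer set of true pocket residues.
#' @return |covered intersect true| / |true|.
#' @export
pocketRecall <- function(covered, trueSet) {
  if (!length(trueSet)) stop("empty true pocket set")
  length(intersect(covered, trueSet)) / length(trueSet)
}

#' Greedy minimal-probe-set selection
#'
#' `coverage[[protein]][[ligand]]` gives the residue set a ligand's
#' prediction covers on a protein (an injected table, or built from a
#' trained model via [predictResidues()] + [predictedCover()]). Proteins are
#' processed in batches; a batch whose mean per-protein recall from the
#' already-selected probes exceeds `coverageThreshold` is skipped. Otherwise
#' the pool ligand adding the most new true-residue coverage (summed over
#' the batch; ties to the lexicographically smaller ligand id) is added,
#' until the batch meets the threshold or no candidate adds coverage.
#'
#' @param coverage named list (by protein id) of named lists (by ligand id)
#'   of integer residue sets.
#' @param trueSets named list of true pocket residue sets per protein;
#'   proteins with empty true sets are excluded with a warning.
#' @param coverageThreshold batch mean-recall skip threshold (default 0.8).
#' @param batchSize proteins per batch (default 32).
#' @param seed optional seed; when given, the protein order is shuffled
#'   before batching (selection within a batch does not depend on protein
#'   order).
#' @return list with `probes` (ordered ligand ids), `covered` (per-protein
#'   covered sets) and `recall` (per-protein recall).
#' @export
greedySelect <- function(coverage, trueSets, coverageThreshold = 0.8,
                         batchSize = 32, seed = NULL) {
  prots <- names(coverage)
  empty <- vapply(trueSets[prots], function(s) !length(s), logical(1))
  if (any(empty)) {
    warning("excluding ", sum(empty), " protein(s) with empty true pocket set")
    prots <- prots[!empty]
  }
  if (!length(prots) || !length(coverage))
    return(list(probes = character(0), covered = list(), recall = numeric(0)))
  pool <- sort(unique(unlist(lapply(coverage, names))))
  if (!length(pool))
    return(list(probes = character(0), covered = list(), recall = numeric(0)))
  if (!is.null(seed)) prots <- withSeed(seed, sample(prots))
  covered <- setNames(lapply(prots, function(p) integer(0)), prots)
  selected <- character(0)
  batches <- split(prots, ceiling(seq_along(prots) / batchSize))
  covSet <- function(p, lig) {
    s <- coverage[[p]][[lig]]
    if (is.null(s)) integer(0) else s
  }
  for (batch in batches) {
    for (p in batch)
      for (lig in selected)
        covered[[p]] <- union(covered[[p]], intersect(covSet(p, lig), trueSets[[p]]))
    meanRecall <- function() mean(vapply(batch, function(p)
      pocketRecall(covered[[p]], trueSets[[p]]), numeric(1)))
    if (meanRecall() > coverageThreshold) next
    repeat {
      gains <- vapply(pool, function(lig) {
        if (lig %in% selected) return(0L)
        sum(vapply(batch, function(p)
          length(setdiff(intersect(covSet(p, lig), trueSets[[p]]),
                         covered[[p]])), integer(1)))
      }, integer(1))
      if (max(gains) == 0L) break
      best <- pool[which(gains == max(gains))][1]  # pool is sorted: lexicographic tie-break
      selected <- c(selected, best)
      for (p in batch)
        covered[[p]] <- union(covered[[p]], intersect(covSet(p, best), trueSets[[p]]))
      if (meanRecall() > coverageThreshold) break
    }
  }
  # final coverage accounting over all proteins
  for (p in prots)
    for (lig in selected)
      covered[[p]] <- union(covered[[p]], intersect(covSet(p, lig), trueSets[[p]]))
  recall <- vapply(prots, function(p) pocketRecall(covered[[p]], trueSets[[p]]),
                   numeric(1))
  list(probes = selected, covered = covered, recall = recall)
}

#' Coverage curve over probe-set prefixes
#'
#' For each prefix of the selected probe set and each recall threshold in
#' `thresholds`, the fraction of proteins whose recall from that prefix
#' exceeds the threshold.
#'
#' @param probes ordered ligand ids (from [greedySelect()]).
#' @param coverage,trueSets as in [greedySelect()].
#' @param thresholds recall threshold grid (default seq(0, 1, 0.05)).
#' @return data.frame with columns prefix, threshold, fraction.
#' @export
coverageCurve <- function(probes, coverage, trueSets,
                          thresholds = seq(0, 1, 0.05)) {
  prots <- names(coverage)
  prots <- prots[vapply(trueSets[prots], length, integer(1)) > 0]
  out <- list()
  for (s in seq_along(probes)) {
    rec <- vapply(prots, function(p) {
      cov <- integer(0)
      for (lig in probes[seq_len(s)])
        cov <- union(cov, coverage[[p]][[lig]])
      pocketRecall(intersect(cov, trueSets[[p]]), trueSets[[p]])
    }, numeric(1))
    out[[s]] <- data.frame(prefix = s, threshold = thresholds,
                           fraction = vapply(thresholds, function(t)
                             mean(rec > t), numeric(1)))
  }
  do.call(rbind, out)
}
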