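# Spatial success metrics for residue-level (Top-K at distance D) and
# coordinate-level (DCA, DCC) predictions.

#' Per-residue minimum distances to the ligand
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligand A \linkS4class{Ligand} with coordinates.
#' @param representation "allatom" (default) or "coarse" residue geometry.
#' @return numeric vector of length m.
#' @export
residueLigandDistances <- function(protein, ligand,
                                   representation = c("allatom", "coarse")) {
  representation <- match.arg(representation)
  makeLabels(protein, ligand, representation = representation)@dMin
}

#' Top-K at distance D residue success
#'
#' Residues are ranked by predicted pocket probability (descending, ties to
#' the lower residue index); the prediction succeeds iff at least one of the
#' top K residues lies within D Angstrom (inclusive) of any ligand heavy
#' atom.
#'
#' @param residueProbs probability vector of length m.
#' @param dMin per-residue minimum ligand distances (e.g. from
#'   [residueLigandDistances()]).
#' @param K number of top residues considered.
#' @param D distance threshold in Angstrom.
#' @return logical.
#' @export
topkSuccess <- function(residueProbs, dMin, K, D) {
  stopifnot(length(residueProbs) == length(dMin))
  ord <- order(-residueProbs, seq_along(residueProbs))
  top <- ord[seq_len(min(K, length(ord)))]
  any(dMin[top] <= D)
}

#' Top-K at distance D success-rate table over a dataset
#'
#' @param probsList list of per-complex residue probability vectors.
#' @param dMinList list of matching per-residue ligand distance vectors.
#' @param Ks vector of K values (default c(1, 3, 10)).
#' @param Ds vector of D thresholds in Angstrom (default 4:10).
#' @return data.frame with columns K, D, rate.
#' @export
topkRateTable <- function(probsList, dMinList, Ks = c(1, 3, 10), Ds = 4:10) {
  stopifnot(length(probsList) == length(dMinList))
  grid <- expand.grid(K = Ks, D = Ds)
  grid$rate <- apply(grid, 1, function(g) {
    mean(mapply(function(p, d) topkSuccess(p, d, g[["K"]], g[["D"]]),
                probsList, dMinList))
  })
  grid
}

#' Distance from a predicted center to the closest ligand atom (DCA)
#'
#' @param center 3-vector.
#' @param ligand A \linkS4class{Ligand} with coordinates, or a coordinate
#'   matrix.
#' @return Angstrom.
#' @export
dca <- function(center, ligand) {
  lig <- if (is(ligand, "Ligand")) ligandCoords(ligand) else as.matrix(ligand)
  min(crossDist(matrix(center, 1), lig))
}

#' Distance from a predicted center to the ligand centroid (DCC)
#'
#' @param center 3-vector.
#' @param ligand A \linkS4class{Ligand} with coordinates, or a coordinate
#'   matrix.
#' @return Angstrom.
#' @export
dcc <- function(center, ligand) {
  lig <- if (is(ligand, "Ligand")) ligandCoords(ligand) else as.matrix(ligand)
  vecNorm(as.numeric(center) - colMeans(lig))
}

#' Coordinate-level success rate over a set of complexes
#'
#' Fraction of complexes where the best of the top `rankBudget` predicted
#' centers has DCA (or DCC) at or below `cutoff`.
#'
#' @param centersList list of center data.frames ([predictCenters()]
#'   output), one per complex.
#' @param ligands list of matching ligands with coordinates.
#' @param cutoff distance cutoff in Angstrom (default 4).
#' @param rankBudget 1 for Top-1, 3 for Top-3 (default 1).
#' @param metric "dca" (default) or "dcc".
#' @return fraction in [0, 1].
#' @export
successRate <- function(centersList, ligands, cutoff = 4, rankBudget = 1,
                        metric = c("dca", "dcc")) {
  metric <- match.arg(metric)
  fn <- if (metric == "dca") dca else dcc
  stopifnot(length(centersList) >= 1)
  mean(mapply(function(cn, lig) {
    cn <- cn[cn$rank <= rankBudget, , drop = FALSE]
    if (!nrow(cn)) return(FALSE)
    any(apply(cn[, c("x", "y", "z")], 1, fn, ligand = lig) <= cutoff)
  }, centersList, ligands))
}

#' Aggregate residue probabilities into one per-complex score
#'
#' @param residueProbs probability vector.
#' @param mode "max" (default) or "mean".
#' @return scalar.
#' @export
aggregateProbability <- function(residueProbs, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(residueProbs) >= 1)
  if (mode == "max") max(residueProbs) else mean(residueProbs)
}
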