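# Ground-truth pocket labels: a residue is part of the binding pocket iff
# its minimum heavy-atom distance to any ligand heavy atom is <= tau (4.0 A).

#' Minimum residue-ligand heavy-atom distance
#'
#' @param residueCoords numeric matrix (k x 3) of residue heavy-atom
#'   coordinates, Angstrom.
#' @param ligand A \linkS4class{Ligand} with 3D coordinates, or a coordinate
#'   matrix.
#' @return Minimum Euclidean distance over all residue-atom/ligand-atom pairs.
#' @export
residueMinDistance <- function(residueCoords, ligand) {
  lig <- if (is(ligand, "Ligand")) ligandCoords(ligand) else as.matrix(ligand)
  if (nrow(residueCoords) < 1) stop("residue has no heavy atom")
  min(crossDist(residueCoords, lig))
}

#' Binary pocket labels from a protein-ligand complex
#'
#' Applies the distance rule y_i = 1 iff d_min,i <= tau with the boundary
#' inclusive. By default d_min,i is taken over all residue heavy atoms;
#' `representation = "coarse"` instead measures from the two coarse-grained
#' points (Calpha and side-chain centroid).
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligand A \linkS4class{Ligand} with 3D coordinates.
#' @param tau distance threshold in Angstrom (default 4.0).
#' @param representation "allatom" (default) or "coarse".
#' @return A \linkS4class{PocketLabels}.
#' @export
makeLabels <- function(protein, ligand, tau = 4.0,
                       representation = c("allatom", "coarse")) {
  representation <- match.arg(representation)
  lig <- ligandCoords(ligand)
  m <- nrow(protein@residues)
  if (representation == "allatom") {
    at <- protein@atoms
    D <- crossDist(as.matrix(at[, c("x", "y", "z")]), lig)
    perAtomMin <- apply(D, 1, min)
    dMin <- as.numeric(tapply(perAtomMin, factor(at$residue,
                                                 levels = protein@residues$index),
                              min))
  } else {
    cg <- coarseGrain(protein)
    D <- crossDist(as.matrix(cg[, c("x", "y", "z")]), lig)
    perNodeMin <- apply(D, 1, min)
    dMin <- as.numeric(tapply(perNodeMin, factor(cg$residue,
                                                 levels = protein@residues$index),
                              min))
  }
  new("PocketLabels", y = as.integer(dMin <= tau), dMin = dMin, tau = tau,
      residues = protein@residues)
}

#' Write pocket labels as TSV
#'
#' Columns: chain, residue number, amino-acid type, d_min, label.
#'
#' @param labels A \linkS4class{PocketLabels}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelsTSV <- function(labels, path) {
  df <- data.frame(chain = labels@residues$chain,
                   resno = labels@residues$resno,
                   aa = labels@residues$aa,
                   d_min = labels@dMin,
                   label = labels@y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
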