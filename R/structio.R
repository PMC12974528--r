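# Structure and ligand input/output.
#
# PDB parsing is delegated to bio3d and chemistry parsing (SDF V2000,
# SMILES) to ChemmineR; this module reshapes their output into the
# package's coarse-grained containers.

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")
ION_RESIDS <- c("NA", "K", "MG", "CA", "ZN", "CL", "MN", "FE", "CU", "NI",
                "CO", "CD", "HG", "SR", "CS", "BA", "LI", "RB", "IOD", "BR",
                "F", "AL", "FE2", "CU1")

#' Parse a protein structure from PDB text or a PDB file
#'
#' Reads ATOM records (first model, first alternate conformer), drops
#' hydrogens, waters and common monoatomic ions, and groups heavy atoms into
#' residues in chain-then-sequence order. Residues lacking a Calpha atom are
#' skipped with a warning; nonstandard residues that do have a Calpha are
#' kept with amino-acid type UNK.
#'
#' @param pdb path to a PDB file, or a character vector/string of PDB text.
#' @return A \linkS4class{ProteinStructure}.
#' @export
parseProtein <- function(pdb) {
  path <- asPdbFile(pdb)
  raw <- suppressWarnings(bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE))
  at <- raw$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- dropNonHeavy(at)
  if (nrow(at) == 0)
    stop("no parsable protein ATOM record in input")
  buildProteinStructure(at)
}

asPdbFile <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  txt <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  f <- tempfile(fileext = ".pdb")
  writeLines(txt, f)
  f
}

dropNonHeavy <- function(at) {
  el <- atomElements(at)
  at$elesy <- el
  at[!(el %in% c("H", "D")), , drop = FALSE]
}

atomElements <- function(at) {
  el <- as.character(at$elesy)
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    guess <- tryCatch(bio3d::atom2ele(at$elety[bad]),
                      error = function(e) rep(NA_character_, sum(bad)))
    el[bad] <- guess
    # last resort: first alphabetic character of the atom name
    still <- is.na(el) | el == ""
    if (any(still))
      el[which(bad)[still[bad]]] <- substr(gsub("[^A-Za-z]", "",
                                                at$elety[bad][still[bad]]), 1, 1)
  }
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

buildProteinStructure <- function(at) {
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  first <- !duplicated(key)
  order_ <- match(key, key[first])
  residues <- data.frame(
    chain = as.character(at$chain[first]),
    resno = at$resno[first],
    insert = ifelse(is.na(at$insert[first]), "", as.character(at$insert[first])),
    aa = toupper(as.character(at$resid[first])),
    stringsAsFactors = FALSE
  )
  hasCa <- vapply(seq_len(nrow(residues)), function(i) {
    any(order_ == i & at$elety == "CA")
  }, logical(1))
  if (any(!hasCa)) {
    warning(sum(!hasCa), " residue(s) without a Calpha atom skipped")
    keep <- which(hasCa)
  } else keep <- seq_len(nrow(residues))
  if (!length(keep)) stop("no residue with a Calpha atom")
  residues <- residues[keep, , drop = FALSE]
  residues$aa <- ifelse(residues$aa %in% AA3, residues$aa, "UNK")
  residues$index <- seq_len(nrow(residues)) - 1L
  newIdx <- rep(NA_integer_, max(order_))
  newIdx[keep] <- residues$index
  atoms <- data.frame(
    element = at$elesy,
    name = as.character(at$elety),
    x = at$x, y = at$y, z = at$z,
    residue = newIdx[order_],
    chain = as.character(at$chain),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!is.na(atoms$residue), , drop = FALSE]
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  new("ProteinStructure", atoms = atoms,
      residues = residues[, c("index", "chain", "resno", "insert", "aa")])
}

#' Coarse-grain a protein into backbone and side-chain nodes
#'
#' Each residue yields exactly two nodes: a backbone (BB) node at the Calpha
#' position and a side-chain (SC) node at the unweighted centroid of the
#' side-chain heavy atoms (all heavy atoms except N, CA, C, O, OXT). Glycine
#' (or any residue with no side-chain heavy atom) places its SC node at the
#' Calpha.
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @return data.frame with 2m rows: residue (0-based), chain, aa, role
#'   ("BB"/"SC"), x, y, z.
#' @export
coarseGrain <- function(protein) {
  res <- protein@residues
  at <- protein@atoms
  backbone <- c("N", "CA", "C", "O", "OXT")
  out <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    ri <- res$index[i]
    ra <- at[at$residue == ri, , drop = FALSE]
    ca <- ra[ra$name == "CA", , drop = FALSE][1, ]
    sc <- ra[!(ra$name %in% backbone), , drop = FALSE]
    scXyz <- if (nrow(sc) == 0) c(ca$x, ca$y, ca$z)
             else c(mean(sc$x), mean(sc$y), mean(sc$z))
    out[[i]] <- data.frame(
      residue = ri, chain = res$chain[i], aa = res$aa[i],
      role = c("BB", "SC"),
      x = c(ca$x, scXyz[1]), y = c(ca$y, scXyz[2]), z = c(ca$z, scXyz[3]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parse a ligand from SDF text/file or a SMILES string
#'
#' Heavy atoms and bonds are extracted; hydrogens (and bonds to them) are
#' removed. SDF input carries 3D coordinates through unchanged; SMILES input
#' yields a connectivity-only (2D) ligand with no coordinates.
#'
#' @param source SDF file path, SDF text, or a SMILES string.
#' @param id identifier stored on the ligand.
#' @return A \linkS4class{Ligand}.
#' @export
parseLigand <- function(source, id = "LIG") {
  isSmiles <- length(source) == 1 && !grepl("\n", source) &&
    !file.exists(source) && !grepl("V2000", source)
  if (isSmiles) {
    sdf <- tryCatch(ChemmineR::smiles2sdf(source),
                    error = function(e) stop("unparsable SMILES: ", source))
    ligandFromSdf(sdf[[1]], id = id, hasCoords = FALSE)
  } else {
    path <- if (length(source) == 1 && file.exists(source)) source else {
      f <- tempfile(fileext = ".sdf")
      writeLines(if (length(source) == 1) strsplit(source, "\n")[[1]] else source, f)
      f
    }
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                       error = function(e) stop("unparsable SDF input"))
    if (length(sdfset) < 1) stop("unparsable SDF input")
    ligandFromSdf(sdfset[[1]], id = id, hasCoords = TRUE)
  }
}

ligandFromSdf <- function(sdf, id, hasCoords) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_[0-9]+$", "", rownames(ab))
  keep <- which(!(elements %in% c("H", "D")))
  if (!length(keep)) stop("ligand has no heavy atom")
  remap <- rep(NA_integer_, length(elements))
  remap[keep] <- seq_along(keep)
  bonds <- matrix(integer(0), 0, 2)
  if (!is.null(bb) && nrow(bb) > 0) {
    b <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    b <- matrix(remap[b], ncol = 2)
    bonds <- b[stats::complete.cases(b), , drop = FALSE]
  }
  atoms <- data.frame(element = elements[keep], stringsAsFactors = FALSE)
  if (hasCoords) {
    atoms$x <- ab[keep, 1]; atoms$y <- ab[keep, 2]; atoms$z <- ab[keep, 3]
  }
  new("Ligand", atoms = atoms, bonds = bonds, id = id, hasCoords = hasCoords)
}

#' Extract candidate ligands from the HETATM records of a PDB file
#'
#' Waters and common monoatomic ions are discarded; remaining hetero heavy
#' atoms are joined into bonds by a covalent distance rule and each connected
#' component becomes one candidate ligand.
#'
#' @param pdb path or PDB text.
#' @return list of \linkS4class{Ligand} objects (possibly empty).
#' @export
ligandsFromPDB <- function(pdb) {
  path <- asPdbFile(pdb)
  raw <- suppressWarnings(bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE))
  at <- raw$atom
  at <- at[at$type == "HETATM", , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% c(WATER_RESIDS, ION_RESIDS)), , drop = FALSE]
  at <- dropNonHeavy(at)
  if (nrow(at) == 0) return(list())
  xyz <- as.matrix(at[, c("x", "y", "z")])
  el <- at$elesy
  D <- crossDist(xyz, xyz)
  long <- el %in% c("S", "P", "Cl", "Br", "I")
  cut <- outer(ifelse(long, 2.1, 1.9), ifelse(long, 2.1, 1.9), pmax)
  bonded <- which(D > 0.4 & D < cut & upper.tri(D), arr.ind = TRUE)
  comp <- componentLabels(nrow(at), bonded)
  lapply(sort(unique(comp)), function(k) {
    idx <- which(comp == k)
    remap <- match(seq_len(nrow(at)), idx)
    b <- bonded[comp[bonded[, 1]] == k, , drop = FALSE]
    new("Ligand",
        atoms = data.frame(element = el[idx], x = xyz[idx, 1],
                           y = xyz[idx, 2], z = xyz[idx, 3],
                           stringsAsFactors = FALSE),
        bonds = matrix(remap[b], ncol = 2),
        id = paste0(at$resid[idx[1]], "_", k),
        hasCoords = TRUE)
  })
}

componentLabels <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (length(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Write a ProteinStructure back to a normalized PDB file
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProteinPDB <- function(protein, path) {
  at <- protein@atoms
  res <- protein@residues
  lookup <- res[match(at$residue, res$index), ]
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
    lookup$aa, lookup$chain, lookup$resno, lookup$insert,
    at$x, at$y, at$z, toupper(at$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the residue indexing map as a JSON sidecar
#'
#' Maps the package's 0-based internal residue indices back to author chain,
#' residue number and insertion code.
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeResidueMap <- function(protein, path) {
  jsonlite::write_json(protein@residues, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
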