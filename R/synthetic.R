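# Synthetic protein-ligand complexes with planted pockets.
#
# The generator emulates the geometry the labeling rule and the graph
# builder care about: a self-avoiding Calpha trace with side-chain
# pseudo-atoms, a ligand placed inside the 4.0 A labeling shell of a
# spatially contiguous residue cluster, decoy ligands, and a learnable
# ligand -> pocket conditioning rule (oxygen/nitrogen-rich ligands bind
# polar pockets, carbon-rich ligands bind hydrophobic pockets).

RULE_AA <- list(A = c("SER", "THR", "ASN", "GLN", "ASP", "GLU"),
                B = c("LEU", "ILE", "VAL", "PHE", "ALA", "MET"))
RULE_ELEMENTS <- list(A = c(C = 0.35, O = 0.40, N = 0.25),
                      B = c(C = 0.90, S = 0.05, F = 0.05))
SC_NAMES <- c("CB", "CG", "CD", "CE")

#' Generate a synthetic protein
#'
#' Self-avoiding 3D walk of Calpha positions with 3.8 A steps and >= 4.0 A
#' separation between non-consecutive residues; each residue receives a
#' random amino-acid type and 1-4 side-chain pseudo-atoms placed 1.5-3.0 A
#' from its Calpha.
#'
#' @param nResidues number of residues (>= 5).
#' @param seed integer seed; the same seed reproduces the structure exactly.
#' @param aaPool amino-acid types to draw from (default the 20 standard).
#' @return A \linkS4class{ProteinStructure}.
#' @export
makeProtein <- function(nResidues, seed, aaPool = AA3) {
  stopifnot(nResidues >= 5)
  withSeed(seed, {
    for (attempt in seq_len(20)) {
      ca <- tryCatch(selfAvoidingWalk(nResidues), error = function(e) NULL)
      if (!is.null(ca)) break
    }
    if (is.null(ca)) stop("Calpha placement failed for seed ", seed)
    aa <- sample(aaPool, nResidues, replace = TRUE)
    atoms <- vector("list", nResidues)
    for (i in seq_len(nResidues)) {
      k <- sample.int(4, 1)
      dirs <- randomUnit(k)
      r <- runif(k, 1.5, 3.0)
      sc <- sweep(dirs * r, 2, ca[i, ], "+")
      atoms[[i]] <- data.frame(
        element = "C",
        name = c("CA", SC_NAMES[seq_len(k)]),
        x = c(ca[i, 1], sc[, 1]), y = c(ca[i, 2], sc[, 2]),
        z = c(ca[i, 3], sc[, 3]),
        residue = i - 1L, chain = "A", stringsAsFactors = FALSE)
    }
    residues <- data.frame(index = seq_len(nResidues) - 1L, chain = "A",
                           resno = seq_len(nResidues), insert = "",
                           aa = aa, stringsAsFactors = FALSE)
    new("ProteinStructure", atoms = do.call(rbind, atoms), residues = residues)
  })
}

selfAvoidingWalk <- function(n, step = 3.8, minSep = 4.0) {
  pos <- matrix(0, n, 3)
  for (i in 2:n) {
    placed <- FALSE
    for (try_ in seq_len(100)) {
      cand <- pos[i - 1, ] + randomUnit(1)[1, ] * step
      if (i == 2 || min(crossDist(matrix(cand, 1), pos[seq_len(i - 2), , drop = FALSE])) >= minSep) {
        pos[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) stop("walk stuck")
  }
  pos
}

randomUnit <- function(k) {
  v <- matrix(rnorm(3 * k), k, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a random connected ligand graph
#'
#' A uniformly random tree over `nAtoms` atoms, optionally closed into one
#' ring; elements are drawn from `elementBias`. The ligand carries no
#' coordinates (2D); [plantComplex()] places it in three dimensions.
#'
#' @param nAtoms number of heavy atoms (>= 1).
#' @param elementBias named probability vector over element symbols.
#' @param seed integer seed.
#' @param ringProb probability of adding one ring-closing bond (default 0.3).
#' @param id ligand identifier.
#' @return A \linkS4class{Ligand} without coordinates.
#' @export
makeLigand <- function(nAtoms, elementBias = c(C = 0.7, N = 0.15, O = 0.15),
                       seed = 1L, ringProb = 0.3, id = NULL) {
  stopifnot(nAtoms >= 1)
  withSeed(seed, {
    elements <- sample(names(elementBias), nAtoms, replace = TRUE,
                       prob = as.numeric(elementBias))
    bonds <- matrix(integer(0), 0, 2)
    if (nAtoms > 1) {
      parents <- vapply(2:nAtoms, function(i) sample.int(i - 1L, 1), integer(1))
      bonds <- cbind(parents, 2:nAtoms)
      if (nAtoms > 3 && runif(1) < ringProb) {
        extra <- sort(sample.int(nAtoms, 2))
        if (!any(bonds[, 1] == extra[1] & bonds[, 2] == extra[2]))
          bonds <- rbind(bonds, extra)
      }
    }
    if (is.null(id)) id <- sprintf("synth-%d-%d", nAtoms, seed)
    new("Ligand", atoms = data.frame(element = elements, stringsAsFactors = FALSE),
        bonds = unname(bonds), id = id, hasCoords = FALSE)
  })
}

#' Plant a ligand into a protein pocket
#'
#' Chooses a spatially contiguous cluster of `pocketSize` residues (a seed
#' residue and its nearest neighbours by Calpha distance) and places each
#' ligand atom 3.0-4.0 A from a heavy atom of a cluster residue while keeping
#' every ligand atom >= 2.5 A from all protein atoms. Atoms are assigned to
#' cluster residues round-robin, so with `atomCount(ligand) >= pocketSize`
#' every planted residue is within the 4.0 A labeling shell of the ligand.
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligand A \linkS4class{Ligand} (its topology is kept; coordinates
#'   are assigned here).
#' @param pocketSize number of planted residues (<= residue count).
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticComplex} (without decoys).
#' @export
plantComplex <- function(protein, ligand, pocketSize, seed) {
  m <- nrow(protein@residues)
  stopifnot(pocketSize <= m)
  n <- atomCount(ligand)
  withSeed(seed, {
    caIdx <- protein@atoms$name == "CA"
    ca <- as.matrix(protein@atoms[caIdx, c("x", "y", "z")])
    ca <- ca[order(protein@atoms$residue[caIdx]), , drop = FALSE]
    protXyz <- as.matrix(protein@atoms[, c("x", "y", "z")])
    for (attempt in seq_len(10)) {
      seedRes <- sample.int(m, 1)
      cluster <- order(crossDist(ca[seedRes, , drop = FALSE], ca)[1, ])[seq_len(pocketSize)]
      coords <- placeLigandAtoms(n, cluster, protein, protXyz)
      if (!is.null(coords)) break
      coords <- NULL
    }
    if (is.null(coords)) stop("no clash-free ligand placement for seed ", seed)
    lig <- ligand
    lig@atoms$x <- coords[, 1]; lig@atoms$y <- coords[, 2]; lig@atoms$z <- coords[, 3]
    lig@hasCoords <- TRUE
    new("SyntheticComplex", protein = protein, trueLigand = lig,
        decoys = list(), plantedPocket = as.integer(sort(cluster)),
        ruleTag = "", seed = as.integer(seed))
  })
}

placeLigandAtoms <- function(n, cluster, protein, protXyz) {
  coords <- matrix(NA_real_, n, 3)
  targets <- cluster[((seq_len(n) - 1L) %% length(cluster)) + 1L]
  for (a in seq_len(n)) {
    ra <- residueAtomCoords(protein, targets[a] - 1L)
    ok <- FALSE
    for (try_ in seq_len(100)) {
      anchor <- ra[sample.int(nrow(ra), 1), ]
      cand <- anchor + randomUnit(1)[1, ] * runif(1, 3.0, 4.0)
      if (min(crossDist(matrix(cand, 1), protXyz)) >= 2.5) {
        coords[a, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) return(NULL)
  }
  coords
}

#' Generate a ligand-conditional synthetic benchmark
#'
#' Each complex is assigned one of two rule classes: class A pairs an
#' oxygen/nitrogen-rich ligand with a pocket whose residues are drawn from
#' polar amino acids; class B pairs a carbon-rich ligand with a hydrophobic
#' pocket. Non-pocket residues are drawn from the amino acids outside the
#' complex's own class set, so the planted conditioning rule is identifiable
#' at small protein sizes. Decoy ligands are drawn from the opposite class
#' and carry no coordinates.
#'
#' @param nComplexes number of complexes.
#' @param seed integer master seed (all randomness derives from it).
#' @param nResidues residues per protein (default 30).
#' @param pocketSize planted pocket size (default 5).
#' @param atomRange range of ligand heavy-atom counts (default 6:9).
#' @param nDecoys decoys per complex (default 10).
#' @return list of \linkS4class{SyntheticComplex}.
#' @export
makeBenchmark <- function(nComplexes, seed, nResidues = 30, pocketSize = 5,
                          atomRange = 6:9, nDecoys = 10) {
  withSeed(seed, {
    subSeeds <- sample.int(.Machine$integer.max - 1L, nComplexes * (nDecoys + 4L))
    classes <- sample(c("A", "B"), nComplexes, replace = TRUE)
    lapply(seq_len(nComplexes), function(i) {
      s <- subSeeds[(i - 1L) * (nDecoys + 4L) + seq_len(nDecoys + 4L)]
      cls <- classes[i]
      other <- if (cls == "A") "B" else "A"
      background <- setdiff(AA3, RULE_AA[[cls]])
      protein <- makeProtein(nResidues, seed = s[1], aaPool = background)
      nA <- max(sample(atomRange, 1), pocketSize)
      lig <- makeLigand(nA, elementBias = RULE_ELEMENTS[[cls]], seed = s[2],
                        id = sprintf("true-%s-%d", cls, i))
      cx <- plantComplex(protein, lig, pocketSize, seed = s[3])
      # enforce the conditioning rule on the planted residues
      pocketAA <- withSeed(s[4], sample(RULE_AA[[cls]],
                                        length(cx@plantedPocket),
                                        replace = TRUE))
      cx@protein@residues$aa[cx@plantedPocket] <- pocketAA
      cx@decoys <- lapply(seq_len(nDecoys), function(k) {
        makeLigand(sample(atomRange, 1),
                   elementBias = RULE_ELEMENTS[[other]], seed = s[4L + k],
                   id = sprintf("decoy-%s-%d-%d", other, i, k))
      })
      cx@ruleTag <- cls
      cx@seed <- as.integer(s[1])
      cx
    })
  })
}

#' Write a synthetic complex as PDB + SDF fixture files
#'
#' @param cx A \linkS4class{SyntheticComplex}.
#' @param dir output directory.
#' @param stem file stem (default "complex").
#' @return character vector of written paths, invisibly.
#' @export
writeComplexFiles <- function(cx, dir, stem = "complex") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(stem, ".pdb"))
  sdf <- file.path(dir, paste0(stem, ".sdf"))
  writeProteinPDB(cx@protein, pdb)
  writeLigandSDF(cx@trueLigand, sdf)
  invisible(c(pdb, sdf))
}

#' Write a ligand as SDF (V2000)
#'
#' @param ligand A \linkS4class{Ligand}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLigandSDF <- function(ligand, path) {
  n <- atomCount(ligand)
  nb <- nrow(ligand@bonds)
  xyz <- if (ligand@hasCoords) ligandCoords(ligand) else matrix(0, n, 3)
  lines <- c(ligand@id, "  pocketgraph", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     xyz[, 1], xyz[, 2], xyz[, 3], ligand@atoms$element))
  if (nb > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0", ligand@bonds[, 1],
                              ligand@bonds[, 2], rep(1L, nb)))
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}
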