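# Shrake-Rupley solvent-accessible-surface probes and their local
# interaction graphs. Each retained surface point is a candidate pocket
# center; the probe node acts as the virtual hub of its local graph.

#' Deterministic spherical Fibonacci lattice
#'
#' @param count number of points (>= 4).
#' @return count x 3 matrix of unit vectors with near-uniform coverage.
#' @export
sphereLattice <- function(count) {
  stopifnot(count >= 4)
  i <- seq_len(count) - 1L
  z <- 1 - 2 * (i + 0.5) / count
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible-surface points
#'
#' For every heavy atom, `count` lattice points are scaled to the expanded
#' radius r_vdw + rProbe and translated to the atom center; a point survives
#' iff its distance to every other atom j is at least r_vdw(j) + rProbe.
#'
#' @param atoms data.frame with columns element, x, y, z (e.g.
#'   `atomTable(protein)`), or a \linkS4class{ProteinStructure}.
#' @param rProbe solvent probe radius in Angstrom (default 1.4).
#' @param count lattice points per atom (default 92).
#' @param radii named van der Waals radius table; defaults to the package
#'   table (C 1.70, N 1.55, O 1.52, S/P 1.80, halogens per Bondi, other
#'   1.70).
#' @return A \linkS4class{SASProbeSet}.
#' @export
shrakeRupley <- function(atoms, rProbe = 1.4, count = 92, radii = VDW_RADII) {
  if (is(atoms, "ProteinStructure")) atoms <- atoms@atoms
  if (nrow(atoms) < 1) stop("empty atom list")
  centers <- as.matrix(atoms[, c("x", "y", "z")])
  rv <- radii[ELEMENT_VOCAB[elementIndex(atoms$element)]]
  rv[is.na(rv)] <- radii[["other"]]
  expanded <- unname(rv) + rProbe
  lattice <- sphereLattice(count)
  keptPts <- vector("list", nrow(atoms))
  keptParent <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    pts <- sweep(lattice * expanded[i], 2, centers[i, ], "+")
    others <- setdiff(seq_len(nrow(atoms)), i)
    ok <- if (length(others)) {
      D <- crossDist(pts, centers[others, , drop = FALSE])
      rowSums(D < matrix(expanded[others], nrow(pts), length(others),
                         byrow = TRUE)) == 0
    } else rep(TRUE, nrow(pts))
    keptPts[[i]] <- pts[ok, , drop = FALSE]
    keptParent[[i]] <- rep(i, sum(ok))
  }
  coords <- do.call(rbind, keptPts)
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 3)
  n <- nrow(coords)
  new("SASProbeSet", coords = coords,
      parentAtom = as.integer(unlist(keptParent)),
      score = rep(NA_real_, n), label = rep(NA_integer_, n))
}

#' Label probes against the ligand center
#'
#' A probe is positive iff its distance to the ligand heavy-atom centroid is
#' strictly below 4.0 Angstrom; otherwise negative.
#'
#' @param probes A \linkS4class{SASProbeSet}.
#' @param ligandCenter 3-vector, or a \linkS4class{Ligand} with coordinates
#'   (its centroid is used).
#' @param threshold positive-label distance in Angstrom (default 4.0).
#' @return The probe set with labels filled in.
#' @export
labelProbes <- function(probes, ligandCenter, threshold = 4.0) {
  if (is(ligandCenter, "Ligand")) ligandCenter <- colMeans(ligandCoords(ligandCenter))
  d <- crossDist(probes@coords, matrix(ligandCenter, 1))[, 1]
  probes@label <- as.integer(d < threshold)
  probes
}

#' Down-sample probes on a voxel grid
#'
#' Keeps the lowest-index probe per cubic voxel; optional speed knob for
#' coordinate-level prediction.
#'
#' @param probes A \linkS4class{SASProbeSet}.
#' @param voxel voxel edge length in Angstrom (default 1.0).
#' @return subset \linkS4class{SASProbeSet}.
#' @export
downsampleProbes <- function(probes, voxel = 1.0) {
  key <- apply(floor(probes@coords / voxel), 1, paste, collapse = ",")
  keep <- which(!duplicated(key))
  new("SASProbeSet", coords = probes@coords[keep, , drop = FALSE],
      parentAtom = probes@parentAtom[keep], score = probes@score[keep],
      label = probes@label[keep])
}

# Shared per-complex context so many probe graphs reuse the coarse-grained
# nodes and intra-protein edges.
probeGraphContext <- function(protein, cutoff = 10) {
  cg <- coarseGrain(protein)
  list(cg = cg, pe = proteinEdges(cg), cutoff = cutoff,
       xyz = as.matrix(cg[, c("x", "y", "z")]))
}

#' Local interaction graph of one probe
#'
#' Nodes: the BB and SC nodes of every residue with at least one node within
#' `cutoff` of the probe, all atoms of the query ligand, and the probe node
#' itself. The probe acts as the virtual hub: probe-residue edges carry
#' I_p_global = 1 with the true probe-node distance, probe-atom edges
#' I_l_global = 1 with d = 0 (the ligand has no pose in this mode; only its
#' connectivity is used). Intra-protein contacts and intra-ligand bonds
#' among included nodes are retained.
#'
#' @param probe 3-vector probe position.
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligand query \linkS4class{Ligand}.
#' @param cutoff residue inclusion cutoff in Angstrom (default 10).
#' @param context optional precomputed [probeGraphContext()] internals.
#' @return A \linkS4class{UnifiedGraph} whose virtual hub is the probe node
#'   (last node).
#' @export
buildProbeGraph <- function(probe, protein, ligand, cutoff = 10,
                            context = NULL) {
  if (is.null(context)) context <- probeGraphContext(protein, cutoff)
  cg <- context$cg
  dProbe <- crossDist(matrix(probe, 1), context$xyz)[1, ]
  resDist <- tapply(dProbe, cg$residue, min)
  inRes <- as.integer(names(resDist))[resDist <= cutoff]
  if (!length(inRes))
    warning("no residue within ", cutoff, " A of the probe")
  nodeSel <- which(cg$residue %in% inRes)
  mLoc <- length(inRes)
  n <- atomCount(ligand)
  remap <- rep(NA_integer_, nrow(cg))
  remap[nodeSel] <- seq_along(nodeSel)
  pe <- context$pe
  keep <- !is.na(remap[pe$src]) & !is.na(remap[pe$dst])
  pe <- pe[keep, , drop = FALSE]
  pe$src <- remap[pe$src]; pe$dst <- remap[pe$dst]
  le <- ligandEdges(ligand)
  le$d <- 0 * le$d  # connectivity-only in probe mode
  if (nrow(le)) { le$src <- le$src + 2L * mLoc; le$dst <- le$dst + 2L * mLoc }
  probeIdx <- 2L * mLoc + n + 1L
  hubP <- if (mLoc) data.frame(src = seq_len(2L * mLoc), dst = probeIdx,
                               d = dProbe[nodeSel], contact = 0, bond = 0,
                               pGlobal = 1, lGlobal = 0) else NULL
  hubL <- data.frame(src = 2L * mLoc + seq_len(n), dst = probeIdx, d = 0,
                     contact = 0, bond = 0, pGlobal = 0, lGlobal = 1)
  base <- rbind(pe, le)
  base$pGlobal <- 0; base$lGlobal <- 0
  edges <- rbind(base, hubP, hubL)
  rownames(edges) <- NULL
  feat <- matrix(0, probeIdx, 34)
  for (k in seq_along(nodeSel)) feat[k, ] <- nodeFeatureRow(aa = cg$aa[nodeSel[k]])
  for (a in seq_len(n)) feat[2L * mLoc + a, ] <- nodeFeatureRow(element = ligand@atoms$element[a])
  feat[probeIdx, ] <- nodeFeatureRow(virtual = TRUE)
  meta <- data.frame(kind = c(rep("protein", 2L * mLoc), rep("ligand", n), "probe"),
                     residue = c(cg$residue[nodeSel], rep(NA_integer_, n + 1L)),
                     role = c(cg$role[nodeSel], rep(NA_character_, n + 1L)),
                     ligand = c(rep(NA_integer_, 2L * mLoc), rep(1L, n), NA_integer_),
                     stringsAsFactors = FALSE)
  new(Class = "UnifiedGraph", nodeFeatures = feat, edges = edges,
      nodeMeta = meta, m = as.integer(mLoc), nAtoms = as.integer(n),
      proteinVirtualIndex = as.integer(probeIdx),
      ligandVirtualIndices = integer(0), C = as.integer(nrow(base)))
}

#' Score SAS probes for one protein-ligand pair
#'
#' Runs the probe-mode network on each probe's local graph and reads a
#' linear head on the final probe-node embedding.
#'
#' @param model A \linkS4class{PocketModel} in probe mode.
#' @param probes A \linkS4class{SASProbeSet}.
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligand query \linkS4class{Ligand}.
#' @param cutoff local-graph residue cutoff (default 10).
#' @return The probe set with scores filled in.
#' @export
scoreProbes <- function(model, probes, protein, ligand, cutoff = 10) {
  if (model@mode != "probe") stop("checkpoint is not a probe-mode model")
  if (!identical(model@vocab$aa, AA_VOCAB))
    stop("checkpoint vocabulary mismatch")
  ctx <- probeGraphContext(protein, cutoff)
  cfg <- model@config
  params <- model@params
  scores <- vapply(seq_len(nrow(probes@coords)), function(i) {
    g <- buildProbeGraph(probes@coords[i, ], protein, ligand,
                         cutoff = cutoff, context = ctx)
    gt <- graphTensors(g, cfg)
    tape <- adTape()
    enc <- buildEncoder(tape, params, gt, cfg)
    h <- adValue(tape, enc$H)[gt$pvi, , drop = FALSE]
    as.numeric(h %*% params$wq + params$bq[1, 1])
  }, numeric(1))
  probes@score <- scores
  probes
}

#' Write probes as CSV and PDB pseudo-atoms
#'
#' @param probes A \linkS4class{SASProbeSet}.
#' @param csvPath CSV output (x, y, z, parent, score, label); NULL to skip.
#' @param pdbPath PDB output (HETATM pseudo-atoms, B-factor = score); NULL to
#'   skip.
#' @return invisibly, the written paths.
#' @export
writeProbes <- function(probes, csvPath = NULL, pdbPath = NULL) {
  if (!is.null(csvPath)) {
    utils::write.csv(data.frame(x = probes@coords[, 1], y = probes@coords[, 2],
                                z = probes@coords[, 3],
                                parent = probes@parentAtom,
                                score = probes@score, label = probes@label),
                     csvPath, row.names = FALSE)
  }
  if (!is.null(pdbPath)) {
    sc <- ifelse(is.na(probes@score), 0, probes@score)
    lines <- sprintf(
      "HETATM%5d  X   PRB A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           X",
      seq_len(nrow(probes@coords)), seq_len(nrow(probes@coords)) %% 10000,
      probes@coords[, 1], probes@coords[, 2], probes@coords[, 3],
      pmin(pmax(sc, -99), 999))
    writeLines(c(lines, "END"), pdbPath)
  }
  invisible(c(csvPath, pdbPath))
}
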