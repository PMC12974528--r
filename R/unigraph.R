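# Unified heterogeneous graph construction.
#
# Node order: residue 1 BB, residue 1 SC, ..., residue m SC (2m protein
# nodes), then ligand 1 atoms, ligand 2 atoms, ..., then the protein virtual
# hub, then one ligand virtual hub per ligand. Cross-molecule information
# flows only through the hubs, so the edge count is C + 2m + sum(n_k)
# (C = backbone + intra-residue + contact + bond edges) rather than
# quadratic in m * n.

#' Protein-internal edges of the coarse-grained graph
#'
#' Three kinds of undirected edges: (a) backbone edges between consecutive
#' residues' BB nodes within a chain, (b) intra-residue BB-SC edges, and (c)
#' contact edges between any two protein nodes strictly closer than `cutoff`.
#' Backbone and intra-residue edges carry the covalent indicator
#' (I_bond = 1), contacts I_contact = 1; duplicates are merged with the
#' indicators OR-ed.
#'
#' @param cg coarse-grained node data.frame from [coarseGrain()].
#' @param cutoff contact distance cutoff in Angstrom (default 8.0, strict <).
#' @return data.frame src, dst, d, contact, bond (src < dst, 1-based row
#'   indices into `cg`).
#' @export
proteinEdges <- function(cg, cutoff = 8.0) {
  n <- nrow(cg)
  xyz <- as.matrix(cg[, c("x", "y", "z")])
  D <- crossDist(xyz, xyz)
  pair <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  edges <- data.frame(src = pair[, 1], dst = pair[, 2],
                      d = D[pair], contact = 1, bond = 0)
  bbRows <- which(cg$role == "BB")
  consec <- which(diff(cg$residue[bbRows]) == 1 &
                  cg$chain[bbRows][-length(bbRows)] == cg$chain[bbRows][-1])
  backbone <- cbind(bbRows[consec], bbRows[consec + 1])
  intra <- cbind(seq(1, n, by = 2), seq(2, n, by = 2))
  cov <- rbind(backbone, intra)
  covKey <- paste(pmin(cov[, 1], cov[, 2]), pmax(cov[, 1], cov[, 2]))
  edgeKey <- paste(edges$src, edges$dst)
  hit <- match(covKey, edgeKey)
  newCov <- which(is.na(hit))
  edges$bond[hit[!is.na(hit)]] <- 1
  if (length(newCov)) {
    a <- pmin(cov[newCov, 1], cov[newCov, 2])
    b <- pmax(cov[newCov, 1], cov[newCov, 2])
    edges <- rbind(edges, data.frame(src = a, dst = b,
                                     d = D[cbind(a, b)], contact = 0, bond = 1))
  }
  edges[order(edges$src, edges$dst), , drop = FALSE]
}

#' Ligand-internal (chemical bond) edges
#'
#' @param ligand A \linkS4class{Ligand}.
#' @return data.frame src, dst, d, contact, bond; d is the bond length when
#'   3D coordinates exist, 0 otherwise (nonspatial edge).
#' @export
ligandEdges <- function(ligand) {
  b <- ligand@bonds
  if (!length(b)) return(data.frame(src = integer(0), dst = integer(0),
                                    d = numeric(0), contact = numeric(0),
                                    bond = numeric(0)))
  d <- if (ligand@hasCoords) {
    xyz <- ligandCoords(ligand)
    sqrt(rowSums((xyz[b[, 1], , drop = FALSE] - xyz[b[, 2], , drop = FALSE])^2))
  } else rep(0, nrow(b))
  data.frame(src = pmin(b[, 1], b[, 2]), dst = pmax(b[, 1], b[, 2]),
             d = d, contact = 0, bond = 1)
}

nodeFeatureRow <- function(aa = NULL, element = NULL, virtual = FALSE) {
  v <- numeric(34)
  if (virtual) v[34] <- 1
  else if (!is.null(aa)) { v[aaIndex(aa)] <- 1; v[32] <- 1 }
  else { v[21 + elementIndex(element)] <- 1; v[33] <- 1 }
  v
}

#' Assemble the unified protein-ligand graph
#'
#' Joins the coarse-grained protein subgraph with one or more ligand
#' subgraphs. A protein virtual hub connects to all 2m structural nodes
#' (I_p_global = 1); each ligand's virtual hub connects to that ligand's
#' atoms and no others (I_l_global = 1). Hub edges are nonspatial (d = 0).
#' The first ligand is the true/query ligand, the rest decoys. There are no
#' direct residue-atom edges. With `hubHubEdge = TRUE` a single
#' protein-hub to true-ligand-hub edge is added (both global indicators set).
#'
#' @param protein A \linkS4class{ProteinStructure}.
#' @param ligands list of \linkS4class{Ligand} (length >= 1).
#' @param cutoff protein contact cutoff in Angstrom.
#' @param hubHubEdge logical, add a protein-hub/ligand-hub edge (default
#'   FALSE).
#' @return A \linkS4class{UnifiedGraph}.
#' @export
assembleGraph <- function(protein, ligands, cutoff = 8.0, hubHubEdge = FALSE) {
  if (is(ligands, "Ligand")) ligands <- list(ligands)
  if (length(ligands) < 1) stop("at least one ligand required")
  cg <- coarseGrain(protein)
  m <- nrow(protein@residues)
  pe <- proteinEdges(cg, cutoff = cutoff)
  nAtoms <- vapply(ligands, atomCount, integer(1))
  offsets <- 2L * m + c(0L, cumsum(nAtoms))[seq_along(ligands)]
  nStruct <- 2L * m + sum(nAtoms)
  pvi <- nStruct + 1L
  lvis <- pvi + seq_along(ligands)

  feat <- matrix(0, nStruct + 1L + length(ligands), 34)
  for (i in seq_len(nrow(cg))) feat[i, ] <- nodeFeatureRow(aa = cg$aa[i])
  meta <- data.frame(kind = c(rep("protein", 2L * m),
                              rep("ligand", sum(nAtoms)),
                              "virtual", rep("virtual", length(ligands))),
                     residue = NA_integer_, role = NA_character_,
                     ligand = NA_integer_, stringsAsFactors = FALSE)
  meta$residue[seq_len(2L * m)] <- cg$residue
  meta$role[seq_len(2L * m)] <- cg$role

  edges <- pe
  edges$pGlobal <- 0; edges$lGlobal <- 0
  for (k in seq_along(ligands)) {
    lig <- ligands[[k]]
    off <- offsets[k]
    for (a in seq_len(nAtoms[k]))
      feat[off + a, ] <- nodeFeatureRow(element = lig@atoms$element[a])
    meta$ligand[off + seq_len(nAtoms[k])] <- k
    le <- ligandEdges(lig)
    if (nrow(le)) {
      le$src <- le$src + off; le$dst <- le$dst + off
      le$pGlobal <- 0; le$lGlobal <- 0
      edges <- rbind(edges, le)
    }
  }
  feat[pvi, ] <- nodeFeatureRow(virtual = TRUE)
  for (k in seq_along(ligands)) feat[lvis[k], ] <- nodeFeatureRow(virtual = TRUE)
  meta$ligand[lvis] <- seq_along(ligands)
  C <- nrow(edges)

  hubP <- data.frame(src = seq_len(2L * m), dst = pvi, d = 0,
                     contact = 0, bond = 0, pGlobal = 1, lGlobal = 0)
  hubL <- do.call(rbind, lapply(seq_along(ligands), function(k) {
    data.frame(src = offsets[k] + seq_len(nAtoms[k]), dst = lvis[k], d = 0,
               contact = 0, bond = 0, pGlobal = 0, lGlobal = 1)
  }))
  edges <- rbind(edges, hubP, hubL)
  if (hubHubEdge)
    edges <- rbind(edges, data.frame(src = pvi, dst = lvis[1], d = 0,
                                     contact = 0, bond = 0, pGlobal = 1,
                                     lGlobal = 1))
  rownames(edges) <- NULL
  new(Class = "UnifiedGraph", nodeFeatures = feat, edges = edges,
      nodeMeta = meta, m = as.integer(m), nAtoms = as.integer(nAtoms),
      proteinVirtualIndex = as.integer(pvi),
      ligandVirtualIndices = as.integer(lvis), C = as.integer(C))
}

#' Sample decoy ligands from a pool
#'
#' Uniform sampling without replacement, excluding the true ligand (by id).
#' If the pool (minus the true ligand) is smaller than `k`, the whole pool is
#' returned with a warning.
#'
#' @param pool list of \linkS4class{Ligand}.
#' @param trueLigand the true ligand (excluded by id).
#' @param k number of decoys requested.
#' @param seed integer seed.
#' @return list of \linkS4class{Ligand} decoys.
#' @export
sampleDecoys <- function(pool, trueLigand, k, seed) {
  ids <- vapply(pool, function(l) l@id, character(1))
  pool <- pool[ids != trueLigand@id]
  if (length(pool) < k) {
    warning("decoy pool smaller than requested; using ", length(pool))
    k <- length(pool)
  }
  withSeed(seed, pool[sample.int(length(pool), k)])
}

#' Serialize a UnifiedGraph to JSON
#'
#' Writes the node table, edge table and bookkeeping indices in a documented
#' JSON container for fixtures and debugging.
#'
#' @param graph A \linkS4class{UnifiedGraph}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphJSON <- function(graph, path) {
  jsonlite::write_json(list(
    m = graph@m, nAtoms = graph@nAtoms,
    proteinVirtualIndex = graph@proteinVirtualIndex,
    ligandVirtualIndices = graph@ligandVirtualIndices,
    C = graph@C,
    nodeFeatures = graph@nodeFeatures,
    nodeMeta = graph@nodeMeta,
    edges = graph@edges
  ), path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
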