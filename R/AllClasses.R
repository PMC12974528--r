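#' @import methods
NULL

#' Parsed protein structure
#'
#' Heavy-atom protein structure grouped into residues. `atoms` holds one row
#' per heavy atom (element, atom name, x/y/z in Angstrom, 0-based internal
#' residue index, chain id); `residues` one row per residue (internal index,
#' chain, author residue number, insertion code, three-letter amino-acid type
#' mapped to the 20 standard types or UNK).
#'
#' @slot atoms data.frame of heavy atoms.
#' @slot residues data.frame of residues in chain, then sequence order.
#' @export
setClass("ProteinStructure", representation(
  atoms = "data.frame",
  residues = "data.frame"
))

setValidity("ProteinStructure", function(object) {
  msgs <- character(0)
  if (nrow(object@residues) < 1) msgs <- c(msgs, "at least one residue required")
  need <- c("element", "name", "x", "y", "z", "residue", "chain")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, "atoms must have element,name,x,y,z,residue,chain")
  if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msgs <- c(msgs, "atom coordinates must be finite")
  if (any(object@atoms$element == "H"))
    msgs <- c(msgs, "hydrogens must not be stored")
  if (length(msgs)) msgs else TRUE
})

#' Small-molecule ligand as a heavy-atom graph
#'
#' @slot atoms data.frame with columns element and (if 3D information is
#'   available) x, y, z in Angstrom; hydrogens excluded.
#' @slot bonds two-column integer matrix of 1-based atom index pairs.
#' @slot id character identifier.
#' @slot hasCoords logical; TRUE when 3D coordinates are present.
#' @export
setClass("Ligand", representation(
  atoms = "data.frame",
  bonds = "matrix",
  id = "character",
  hasCoords = "logical"
))

setValidity("Ligand", function(object) {
  msgs <- character(0)
  n <- nrow(object@atoms)
  if (n < 1) msgs <- c(msgs, "ligand needs at least one atom")
  b <- object@bonds
  if (length(b) && (any(b < 1) || any(b > n)))
    msgs <- c(msgs, "bond endpoints out of range")
  if (any(object@atoms$element == "H"))
    msgs <- c(msgs, "hydrogens must be excluded")
  if (n > 1 && !isConnectedGraph(n, b))
    msgs <- c(msgs, "ligand graph must be connected")
  if (length(msgs)) msgs else TRUE
})

# Connectivity check via breadth-first search over the bond list.
isConnectedGraph <- function(n, bonds) {
  if (n <= 1) return(TRUE)
  if (!length(bonds)) return(FALSE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Unified heterogeneous protein-ligand graph
#'
#' One protein (2m backbone/side-chain nodes plus a protein virtual hub) and
#' k ligands (atoms plus one ligand virtual hub each), with 5-dimensional
#' edge features [d_ij, I_contact, I_bond, I_p_global, I_l_global]. The first
#' ligand is the true (query) ligand; any others are decoys.
#'
#' @slot nodeFeatures numeric matrix, one row per node (21 amino-acid one-hot
#'   incl. UNK, 10 element one-hot incl. other, 3 node-type mask bits).
#' @slot edges data.frame with columns src, dst, d, contact, bond, pGlobal,
#'   lGlobal; each undirected edge stored once.
#' @slot nodeMeta data.frame bookkeeping (kind, residue, role, ligand).
#' @slot m integer residue count.
#' @slot nAtoms integer vector of per-ligand heavy-atom counts.
#' @slot proteinVirtualIndex integer node index of the protein hub.
#' @slot ligandVirtualIndices integer node indices of the ligand hubs.
#' @slot C integer count of backbone + intra-residue + contact + bond edges.
#' @export
setClass("UnifiedGraph", representation(
  nodeFeatures = "matrix",
  edges = "data.frame",
  nodeMeta = "data.frame",
  m = "integer",
  nAtoms = "integer",
  proteinVirtualIndex = "integer",
  ligandVirtualIndices = "integer",
  C = "integer"
))

setValidity("UnifiedGraph", function(object) {
  msgs <- character(0)
  X <- object@nodeFeatures
  if (ncol(X) != 34) msgs <- c(msgs, "node features must be 21+10+3 = 34 wide")
  masks <- X[, 32:34, drop = FALSE]
  if (any(rowSums(masks) != 1)) msgs <- c(msgs, "exactly one mask bit per node")
  aaBlock <- rowSums(X[, 1:21, drop = FALSE])
  elBlock <- rowSums(X[, 22:31, drop = FALSE])
  if (any(aaBlock > 0 & masks[, 1] == 0))
    msgs <- c(msgs, "amino-acid one-hot set on a non-protein node")
  if (any(elBlock > 0 & masks[, 2] == 0))
    msgs <- c(msgs, "element one-hot set on a non-ligand node")
  if (any(masks[, 3] == 1 & (aaBlock + elBlock) > 0))
    msgs <- c(msgs, "virtual nodes must have zero one-hot blocks")
  e <- object@edges
  ind <- as.matrix(e[, c("contact", "bond", "pGlobal", "lGlobal")])
  if (length(ind) && any(rowSums(ind) < 1))
    msgs <- c(msgs, "every edge needs at least one indicator")
  hub <- sum((e$pGlobal == 1) + (e$lGlobal == 1) == 1)
  if (hub != 2L * object@m + sum(object@nAtoms))
    msgs <- c(msgs, "hub edge count must equal 2m + sum(n_k)")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth pocket labels for one complex
#'
#' @slot y integer 0/1 vector over residues; y_i = 1 iff dMin_i <= tau.
#' @slot dMin numeric per-residue minimum residue-ligand heavy-atom distance
#'   in Angstrom.
#' @slot tau numeric threshold in Angstrom (default 4.0).
#' @slot residues data.frame copied from the protein for reporting.
#' @export
setClass("PocketLabels", representation(
  y = "integer",
  dMin = "numeric",
  tau = "numeric",
  residues = "data.frame"
))

setValidity("PocketLabels", function(object) {
  msgs <- character(0)
  if (length(object@y) != length(object@dMin))
    msgs <- c(msgs, "y and dMin lengths differ")
  if (!all(object@y == as.integer(object@dMin <= object@tau)))
    msgs <- c(msgs, "labels inconsistent with the distance rule")
  if (length(msgs)) msgs else TRUE
})

#' Trained message-passing model (checkpoint)
#'
#' @slot params named list of weight matrices.
#' @slot config model configuration list (numLayers, hiddenDim, dScale, ...).
#' @slot vocab list of amino-acid and element vocabularies used at training.
#' @slot history data.frame loss history (may be empty).
#' @slot mode character: "residue" or "probe".
#' @export
setClass("PocketModel", representation(
  params = "list",
  config = "list",
  vocab = "list",
  history = "data.frame",
  mode = "character"
))

#' Scored solvent-accessible-surface probes
#'
#' @slot coords numeric matrix (n x 3) of probe positions, Angstrom.
#' @slot parentAtom integer index of the atom each probe sits on.
#' @slot score numeric per-probe score (NA until scored).
#' @slot label integer 1 = positive, 0 = negative, NA = unset.
#' @export
setClass("SASProbeSet", representation(
  coords = "matrix",
  parentAtom = "integer",
  score = "numeric",
  label = "integer"
))

#' Synthetic protein-ligand complex with a planted pocket
#'
#' @slot protein ProteinStructure.
#' @slot trueLigand Ligand with 3D coordinates placed in the planted pocket.
#' @slot decoys list of Ligand objects without coordinates.
#' @slot plantedPocket integer vector of planted residue indices (1-based).
#' @slot ruleTag character class tag of the conditioning rule ("A"/"B").
#' @slot seed integer seed that generated the complex.
#' @export
setClass("SyntheticComplex", representation(
  protein = "ProteinStructure",
  trueLigand = "Ligand",
  decoys = "list",
  plantedPocket = "integer",
  ruleTag = "character",
  seed = "integer"
))

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure:", nrow(object@residues), "residues,",
      nrow(object@atoms), "heavy atoms,",
      length(unique(object@residues$chain)), "chain(s)\n")
})

setMethod("show", "Ligand", function(object) {
  cat("Ligand", object@id, ":", nrow(object@atoms), "heavy atoms,",
      nrow(object@bonds), "bonds,",
      if (object@hasCoords) "3D" else "2D", "\n")
})

setMethod("show", "UnifiedGraph", function(object) {
  cat("UnifiedGraph: m =", object@m, "residues,",
      length(object@nAtoms), "ligand(s) with",
      paste(object@nAtoms, collapse = "+"), "atoms;",
      nrow(object@nodeFeatures), "nodes,", nrow(object@edges),
      "undirected edges (C =", object@C, ")\n")
})

setMethod("show", "PocketLabels", function(object) {
  cat("PocketLabels: m =", length(object@y), ", positives =", sum(object@y),
      ", tau =", object@tau, "A\n")
})

setMethod("show", "PocketModel", function(object) {
  cfg <- object@config
  cat("PocketModel (", object@mode, " mode): ", cfg$numLayers, " layers x ",
      cfg$hiddenDim, " hidden; ", sum(vapply(object@params, length, integer(1))),
      " parameters\n", sep = "")
})

setMethod("show", "SASProbeSet", function(object) {
  cat("SASProbeSet:", nrow(object@coords), "probes;",
      sum(!is.na(object@score)), "scored;",
      sum(object@label == 1, na.rm = TRUE), "positive\n")
})

setMethod("show", "SyntheticComplex", function(object) {
  cat("SyntheticComplex (rule ", object@ruleTag, "): m = ",
      nrow(object@protein@residues), ", planted pocket of ",
      length(object@plantedPocket), " residues, ",
      length(object@decoys), " decoys\n", sep = "")
})

#' @rdname ProteinStructure-class
#' @param object,x a ProteinStructure
#' @export
residueCount <- function(x) nrow(x@residues)

#' @rdname ProteinStructure-class
#' @export
residueTable <- function(x) x@residues

#' @rdname ProteinStructure-class
#' @export
atomTable <- function(x) x@atoms

#' @rdname Ligand-class
#' @param x a Ligand
#' @export
atomCount <- function(x) nrow(x@atoms)

#' @rdname Ligand-class
#' @export
ligandCoords <- function(x) {
  if (!x@hasCoords) stop("ligand has no 3D coordinates")
  as.matrix(x@atoms[, c("x", "y", "z")])
}

# Heavy atoms of one residue (by internal 0-based index) as a coordinate matrix.
residueAtomCoords <- function(protein, residueIndex) {
  a <- protein@atoms[protein@atoms$residue == residueIndex, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
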