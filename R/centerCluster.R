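# Condense scored surface probes into ranked pocket centers: each probe
# climbs to its highest-scoring strictly-better neighbor within a radius;
# probes converging to the same local peak form one cluster (union-find),
# and clusters are ranked by peak score.

#' Hill-climbing parent assignment
#'
#' Each point's parent is the neighbor within `radius` (excluding itself)
#' with the highest score strictly greater than its own; ties among equally
#' scored better neighbors break to the lower point index. Points with no
#' strictly better neighbor are peaks (their own parent). Scores strictly
#' increase along parent chains, so iteration terminates.
#'
#' @param points n x 3 coordinate matrix.
#' @param scores numeric vector of length n.
#' @param radius neighborhood radius in Angstrom (> 0).
#' @return integer parent vector of length n.
#' @export
hillClimb <- function(points, scores, radius) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(nrow(points) == length(scores), radius > 0)
  n <- nrow(points)
  D <- crossDist(points, points)
  parent <- seq_len(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] <= radius & seq_len(n) != i & scores > scores[i])
    if (length(nb)) parent[i] <- nb[which.max(scores[nb])]
  }
  parent
}

#' Group a hill-climbing forest into ranked clusters
#'
#' Connected components under the parent links; each component's root is its
#' peak. Clusters are sorted by peak score descending (ties to the lower
#' peak index) and ranked 1..K.
#'
#' @param parent integer parent vector from [hillClimb()].
#' @param scores the scores used for climbing.
#' @param points optional coordinates; when given, each cluster's center
#'   (the peak's coordinates) is attached.
#' @return list with `assignment` (cluster rank per point) and `clusters`, a
#'   data.frame (rank, peakIndex, peakScore, size, and center columns when
#'   points are supplied).
#' @export
unionFindClusters <- function(parent, scores, points = NULL) {
  n <- length(parent)
  root <- seq_len(n)
  for (i in seq_len(n)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    # path compression
    j <- i
    while (parent[j] != r) { nxt <- parent[j]; parent[j] <- r; j <- nxt }
    root[i] <- r
  }
  peaks <- unique(root)
  ord <- order(-scores[peaks], peaks)
  peaks <- peaks[ord]
  ranks <- match(root, peaks)
  clusters <- data.frame(rank = seq_along(peaks), peakIndex = peaks,
                         peakScore = scores[peaks],
                         size = as.integer(table(factor(ranks,
                                                        levels = seq_along(peaks)))))
  if (!is.null(points)) {
    points <- matrix(as.numeric(points), ncol = 3)
    clusters$x <- points[peaks, 1]
    clusters$y <- points[peaks, 2]
    clusters$z <- points[peaks, 3]
  }
  list(assignment = ranks, clusters = clusters)
}

#' Predicted pocket centers from scored probes
#'
#' Runs hill climbing and union-find grouping on the scored probe set and
#' returns the top `topK` cluster peaks, in rank order, as predicted pocket
#' centers.
#'
#' @param probes A \linkS4class{SASProbeSet} with scores set.
#' @param radius climbing neighborhood radius in Angstrom (default 3.0).
#' @param topK number of centers requested (default 3); if fewer clusters
#'   exist, all are returned with a warning.
#' @return data.frame of ranked centers (rank, x, y, z, peakScore, size).
#' @export
predictCenters <- function(probes, radius = 3.0, topK = 3) {
  if (anyNA(probes@score)) stop("probes must be scored first")
  parent <- hillClimb(probes@coords, probes@score, radius)
  uf <- unionFindClusters(parent, probes@score, probes@coords)
  cl <- uf$clusters
  if (nrow(cl) < topK)
    warning("only ", nrow(cl), " cluster(s) available; returning all")
  cl[seq_len(min(topK, nrow(cl))), c("rank", "x", "y", "z", "peakScore", "size")]
}

#' Write predicted centers as CSV and/or PDB
#'
#' @param centers data.frame from [predictCenters()].
#' @param csvPath CSV path or NULL.
#' @param pdbPath PDB path (HETATM records, B-factor = peak score) or NULL.
#' @return invisibly, the written paths.
#' @export
writeCenters <- function(centers, csvPath = NULL, pdbPath = NULL) {
  if (!is.null(csvPath)) utils::write.csv(centers, csvPath, row.names = FALSE)
  if (!is.null(pdbPath)) {
    lines <- sprintf(
      "HETATM%5d  C   CTR A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
      centers$rank, centers$rank, centers$x, centers$y, centers$z,
      pmin(pmax(centers$peakScore, -99), 999))
    writeLines(c(lines, "END"), pdbPath)
  }
  invisible(c(csvPath, pdbPath))
}
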