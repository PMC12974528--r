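#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.csv head
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# All pairwise Euclidean distances between the rows of two n x 3 matrices.
crossDist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

vecNorm <- function(v) sqrt(sum(v^2))

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Scatter-add the rows of `g` into an n-row matrix at positions `idx`
# (duplicated indices accumulate).
scatterRows <- function(g, idx, n) {
  out <- matrix(0, n, ncol(g))
  agg <- rowsum(g, group = idx, reorder = FALSE)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# Amino-acid and element vocabularies used for one-hot node features.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA_VOCAB <- c(AA3, "UNK")
ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")

aaIndex <- function(aa) {
  i <- match(toupper(aa), AA_VOCAB)
  ifelse(is.na(i), length(AA_VOCAB), i)
}

elementIndex <- function(el) {
  el <- as.character(el)
  canon <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  i <- match(canon, ELEMENT_VOCAB)
  ifelse(is.na(i), length(ELEMENT_VOCAB), i)
}

# Van der Waals radii (Angstrom), Bondi-style values; "other" falls back to C.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, other = 1.70)

vdwRadius <- function(el) {
  unname(VDW_RADII[ELEMENT_VOCAB[elementIndex(el)]])
}
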