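mkResidue <- function(i, x, aa = "ALA", chain = "A") {
  data.frame(element = "C", name = c("CA", "CB"), x = c(x, x), y = c(0, 1.5),
             z = 0, residue = i, chain = chain)
}

lineProtein <- function(n, spacing = 3.8) {
  atoms <- do.call(rbind, lapply(seq_len(n) - 1L,
                                 function(i) mkResidue(i, i * spacing)))
  new("ProteinStructure", atoms = atoms,
      residues = data.frame(index = seq_len(n) - 1L, chain = "A",
                            resno = seq_len(n), insert = "", aa = "ALA"))
}

test_that("contact edges use a strict 8.0 A cutoff", {
  twoCa <- function(d) {
    atoms <- rbind(
      data.frame(element = "C", name = "CA", x = 0, y = 0, z = 0,
                 residue = 0L, chain = "A"),
      data.frame(element = "C", name = "CA", x = d, y = 0, z = 0,
                 residue = 1L, chain = "B"))
    new("ProteinStructure", atoms = atoms,
        residues = data.frame(index = 0:1, chain = c("A", "B"), resno = 1:2,
                              insert = "", aa = "GLY"))
  }
  # different chains, so no backbone edge; glycine SC sits on CA so the only
  # BB-BB candidate is the cross-residue contact
  cgNear <- coarseGrain(twoCa(7.9))
  eNear <- proteinEdges(cgNear)
  bbPair <- eNear[eNear$src == 1 & eNear$dst == 3, ]
  expect_equal(nrow(bbPair), 1)
  expect_equal(bbPair$d, 7.9)
  expect_equal(bbPair$contact, 1)
  cgFar <- coarseGrain(twoCa(8.0))
  eFar <- proteinEdges(cgFar)
  expect_equal(nrow(eFar[eFar$src == 1 & eFar$dst == 3, ]), 0)
})

test_that("an isolated chain has backbone and intra-residue edges only", {
  # 10 residues spaced 9 A apart: no contacts, 9 backbone + 10 intra edges
  p <- lineProtein(10, spacing = 9)
  cg <- coarseGrain(p)
  e <- proteinEdges(cg)
  expect_equal(sum(e$bond), 19)
  expect_equal(nrow(e), 19)
  # enumeration oracle: backbone pairs (2i-1, 2i+1), intra pairs (2i-1, 2i)
  bb <- cbind(seq(1, 17, 2), seq(3, 19, 2))
  intra <- cbind(seq(1, 19, 2), seq(2, 20, 2))
  got <- e[, c("src", "dst")]
  want <- rbind(bb, intra)
  expect_setequal(paste(got$src, got$dst),
                  paste(pmin(want[, 1], want[, 2]), pmax(want[, 1], want[, 2])))
})

test_that("ligand edges carry the bond indicator and bond-length distances", {
  eth <- parseLigand(paste(ethanolSdf3D(), collapse = "\n"))
  le <- ligandEdges(eth)
  expect_equal(nrow(le), 2)
  expect_true(all(le$bond == 1))
  xyz <- ligandCoords(eth)
  expect_equal(le$d[1], sqrt(sum((xyz[1, ] - xyz[2, ])^2)))
  # 2D ligand: nonspatial edges have d = 0
  smi <- parseLigand("C1CCCCC1")
  expect_equal(nrow(ligandEdges(smi)), 6)
  expect_true(all(ligandEdges(smi)$d == 0))
})

test_that("assembled graph has the C + 2m + sum(n) edge count", {
  # m = 3 line protein, far spacing; ligand with 2 atoms, 1 bond
  p <- lineProtein(3, spacing = 9)
  lig <- new("Ligand", atoms = data.frame(element = c("C", "O")),
             bonds = matrix(c(1L, 2L), 1), id = "L", hasCoords = FALSE)
  g <- assembleGraph(p, list(lig))
  # enumeration: 2 backbone + 3 intra + 1 bond = C = 6; hub = 6 + 2
  expect_equal(g@C, 6L)
  expect_equal(nrow(g@edges), 6 + 2 * 3 + 2)
  expect_true(validObject(g))
})

test_that("hub wiring: protein hub spans 2m nodes, ligand hubs their atoms", {
  cx <- smallBenchmark()[[1]]
  g <- assembleGraph(cx@protein, c(list(cx@trueLigand), cx@decoys[1:2]))
  e <- g@edges
  hubP <- e[e$pGlobal == 1, ]
  expect_setequal(hubP$src, seq_len(2 * g@m))
  expect_true(all(hubP$dst == g@proteinVirtualIndex))
  expect_true(all(hubP$d == 0))
  for (k in seq_along(g@nAtoms)) {
    hubL <- e[e$lGlobal == 1 & e$dst == g@ligandVirtualIndices[k], ]
    expect_equal(nrow(hubL), g@nAtoms[k])
    expect_setequal(g@nodeMeta$ligand[hubL$src], k)
  }
  # no direct residue-atom edges
  kinds <- g@nodeMeta$kind
  cross <- kinds[e$src] == "protein" & kinds[e$dst] == "ligand" |
           kinds[e$src] == "ligand" & kinds[e$dst] == "protein"
  expect_false(any(cross))
})

test_that("node features satisfy one-hot/mask exclusivity on random graphs", {
  for (cx in smallBenchmark()[1:3]) {
    g <- assembleGraph(cx@protein, c(list(cx@trueLigand), cx@decoys))
    X <- g@nodeFeatures
    expect_true(all(rowSums(X[, 32:34]) == 1))
    expect_true(all(rowSums(X[, 1:21]) == X[, 32]))
    expect_true(all(rowSums(X[, 22:31]) == X[, 33]))
  }
})

test_that("hub edge count scales linearly: (edges - C) = 2m + n exactly", {
  lig <- makeLigand(8, seed = 21)
  for (m in c(50, 100, 200, 400)) {
    p <- makeProtein(m, seed = 100 + m)
    g <- assembleGraph(p, list(lig))
    expect_equal(nrow(g@edges) - g@C, 2L * m + atomCount(lig))
    expect_equal((nrow(g@edges) - g@C) / (2 * m + atomCount(lig)), 1)
  }
})

test_that("1 true + 50 decoys yields 51 ligand virtual nodes", {
  p <- makeProtein(10, seed = 4)
  ligs <- lapply(1:51, function(i) makeLigand(4, seed = i))
  g <- assembleGraph(p, ligs)
  expect_length(g@ligandVirtualIndices, 51)
  expect_equal(sum(g@nodeMeta$kind == "virtual"), 52)
})

test_that("decoy sampling excludes the true ligand and respects the pool", {
  pool <- lapply(1:6, function(i) makeLigand(4, seed = i, id = paste0("L", i)))
  true_ <- pool[[3]]
  d <- sampleDecoys(pool, true_, 4, seed = 8)
  expect_length(d, 4)
  expect_false("L3" %in% vapply(d, function(x) x@id, character(1)))
  expect_warning(sampleDecoys(pool, true_, 10, seed = 8), "pool smaller")
  # determinism
  d2 <- sampleDecoys(pool, true_, 4, seed = 8)
  expect_identical(vapply(d, function(x) x@id, character(1)),
                   vapply(d2, function(x) x@id, character(1)))
})

test_that("graph JSON serialization round-trips the edge table", {
  cx <- smallBenchmark()[[1]]
  g <- assembleGraph(cx@protein, list(cx@trueLigand))
  f <- tempfile(fileext = ".json")
  writeGraphJSON(g, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$m, g@m)
  expect_equal(back$C, g@C)
  expect_equal(back$edges$src, g@edges$src)
  expect_equal(back$edges$d, g@edges$d, tolerance = 1e-12)
})
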