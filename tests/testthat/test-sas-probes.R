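test_that("the sphere lattice is unit-norm, balanced and deterministic", {
  v <- sphereLattice(92)
  expect_equal(dim(v), c(92, 3))
  expect_equal(sqrt(rowSums(v^2)), rep(1, 92), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(v)^2)), 0.05)
  expect_identical(v, sphereLattice(92))
  expect_error(sphereLattice(2))
})

test_that("an isolated carbon keeps every lattice point at 3.10 A", {
  atoms <- data.frame(element = "C", x = 0, y = 0, z = 0)
  pr <- shrakeRupley(atoms, count = 92)
  expect_equal(nrow(pr@coords), 92)
  expect_equal(sqrt(rowSums(pr@coords^2)), rep(3.10, 92), tolerance = 1e-12)
})

test_that("distant atoms do not occlude each other", {
  atoms <- data.frame(element = "C", x = c(0, 100), y = 0, z = 0)
  pr <- shrakeRupley(atoms, count = 48)
  expect_equal(nrow(pr@coords), 96)
})

test_that("occlusion filtering equals the brute-force oracle point by point", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      nAt <- sample(3:10, 1)
      atoms <- data.frame(element = sample(c("C", "N", "O", "S"), nAt, TRUE),
                          x = runif(nAt, 0, 6), y = runif(nAt, 0, 6),
                          z = runif(nAt, 0, 6))
      count <- 32
      pr <- shrakeRupley(atoms, count = count)
      # independent O(points x atoms) oracle with scalar loops
      lattice <- sphereLattice(count)
      rv <- vapply(atoms$element,
                   function(e) pocketgraph:::vdwRadius(e), numeric(1))
      keptOracle <- list()
      for (i in seq_len(nAt)) {
        for (k in seq_len(count)) {
          pt <- c(atoms$x[i], atoms$y[i], atoms$z[i]) + lattice[k, ] * (rv[i] + 1.4)
          ok <- TRUE
          for (j in seq_len(nAt)) {
            if (j == i) next
            dj <- sqrt(sum((pt - c(atoms$x[j], atoms$y[j], atoms$z[j]))^2))
            if (dj < rv[j] + 1.4) { ok <- FALSE; break }
          }
          if (ok) keptOracle[[length(keptOracle) + 1L]] <- c(pt, i)
        }
      }
      oracle <- do.call(rbind, keptOracle)
      if (is.null(oracle)) {
        expect_equal(nrow(pr@coords), 0)
      } else {
        expect_equal(nrow(pr@coords), nrow(oracle))
        expect_equal(pr@coords, oracle[, 1:3], tolerance = 1e-12,
                     ignore_attr = TRUE)
        expect_equal(pr@parentAtom, as.integer(oracle[, 4]))
      }
    }
  })
})

test_that("every retained point is on its parent's expanded sphere and clear of others", {
  cx <- smallBenchmark()[[1]]
  pr <- shrakeRupley(cx@protein@atoms, count = 16)
  at <- cx@protein@atoms
  rv <- vapply(at$element, function(e) pocketgraph:::vdwRadius(e), numeric(1))
  centers <- as.matrix(at[, c("x", "y", "z")])
  for (i in seq_len(min(nrow(pr@coords), 200))) {
    p <- pr@coords[i, ]; parent <- pr@parentAtom[i]
    expect_equal(sqrt(sum((p - centers[parent, ])^2)),
                 unname(rv[parent]) + 1.4, tolerance = 1e-10)
    d <- sqrt(rowSums(sweep(centers[-parent, , drop = FALSE], 2, p)^2))
    expect_true(all(d >= rv[-parent] + 1.4 - 1e-10))
  }
})

test_that("probe count never increases as atoms are added", {
  atoms <- data.frame(element = "C",
                      x = c(0, 2, 3), y = c(0, 0.5, 1), z = 0)
  n1 <- nrow(shrakeRupley(atoms[1, , drop = FALSE], count = 32)@coords)
  n12 <- shrakeRupley(atoms[1:2, , drop = FALSE], count = 32)
  # points surviving on atom 1 can only be lost, never gained
  expect_lte(sum(n12@parentAtom == 1), n1)
})

test_that("probe labeling uses a strict 4.0 A rule against the ligand center", {
  probes <- new("SASProbeSet",
                coords = rbind(c(3.9, 0, 0), c(4.0, 0, 0), c(0, 0, 0)),
                parentAtom = c(1L, 1L, 1L), score = rep(NA_real_, 3),
                label = rep(NA_integer_, 3))
  lab <- labelProbes(probes, c(0, 0, 0))
  expect_equal(lab@label, c(1L, 0L, 1L))
})

test_that("probe local graphs include exactly the residues within the cutoff", {
  cx <- smallBenchmark()[[1]]
  cg <- coarseGrain(cx@protein)
  probe <- colMeans(ligandCoords(cx@trueLigand))
  g <- buildProbeGraph(probe, cx@protein, cx@trueLigand, cutoff = 10)
  # enumeration oracle
  d <- pocketgraph:::crossDist(matrix(probe, 1),
                               as.matrix(cg[, c("x", "y", "z")]))[1, ]
  wantRes <- sort(unique(cg$residue[cg$residue %in%
    as.integer(names(which(tapply(d, cg$residue, min) <= 10)))]))
  gotRes <- sort(unique(g@nodeMeta$residue[g@nodeMeta$kind == "protein"]))
  expect_equal(gotRes, wantRes)
  # hub degree = included residue nodes + ligand atoms
  e <- g@edges
  hub <- e[e$dst == g@proteinVirtualIndex | e$src == g@proteinVirtualIndex, ]
  expect_equal(nrow(hub), 2 * length(wantRes) + atomCount(cx@trueLigand))
  expect_true(validObject(g))
})

test_that("a far-away probe warns about an empty local context", {
  cx <- smallBenchmark()[[1]]
  expect_warning(buildProbeGraph(c(1e4, 1e4, 1e4), cx@protein,
                                 cx@trueLigand, cutoff = 10),
                 "no residue within")
})

test_that("probe scoring is deterministic and checks the mode", {
  cx <- smallBenchmark()[[1]]
  probes <- labelProbes(shrakeRupley(cx@protein@atoms, count = 8),
                        colMeans(ligandCoords(cx@trueLigand)))
  pm <- initModel(modelConfig(1, 8, seed = 6), mode = "probe")
  s1 <- scoreProbes(pm, probes, cx@protein, cx@trueLigand)
  s2 <- scoreProbes(pm, probes, cx@protein, cx@trueLigand)
  expect_identical(s1@score, s2@score)
  rm_ <- initModel(modelConfig(1, 8, seed = 6), mode = "residue")
  expect_error(scoreProbes(rm_, probes, cx@protein, cx@trueLigand),
               "not a probe-mode")
})

test_that("probes export to CSV and PDB pseudo-atom files", {
  probes <- new("SASProbeSet",
                coords = rbind(c(1, 2, 3), c(4, 5, 6)),
                parentAtom = c(1L, 2L), score = c(0.5, -0.25),
                label = c(1L, 0L))
  csv <- tempfile(fileext = ".csv"); pdb <- tempfile(fileext = ".pdb")
  writeProbes(probes, csvPath = csv, pdbPath = pdb)
  back <- read.csv(csv)
  expect_equal(back$score, c(0.5, -0.25))
  expect_equal(back$label, c(1L, 0L))
  lines <- readLines(pdb)
  expect_equal(sum(startsWith(lines, "HETATM")), 2)
})

test_that("voxel down-sampling keeps at most one probe per voxel", {
  probes <- new("SASProbeSet",
                coords = rbind(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2),
                               c(5, 5, 5)),
                parentAtom = 1:3, score = rep(NA_real_, 3),
                label = rep(NA_integer_, 3))
  ds <- downsampleProbes(probes, voxel = 1.0)
  expect_equal(nrow(ds@coords), 2)
  expect_equal(ds@parentAtom, c(1L, 3L))
})
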