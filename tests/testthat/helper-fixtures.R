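# Shared fixtures, built in code at test time.

# Minimal two-residue PDB fragment (ALA with CB side chain, GLY) plus a
# water that parsers must drop.
tinyPdbText <- function() {
  c("ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   2.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   2.500   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       3.000   3.000   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.500   2.000   1.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       4.500   2.500   2.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.500   3.000   1.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.500   3.500   1.500  1.00  0.00           O",
    "HETATM   10  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
}

altlocPdbText <- function() {
  c("ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   2.000   2.000  1.00  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   2.500   2.500  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   2.500   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       3.000   3.000   0.000  1.00  0.00           O",
    "END")
}

# Methane SDF with explicit hydrogens (heavy-atom parsing must keep 1 atom).
methaneSdf <- function() {
  c("methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END", "$$$$")
}

ethanolSdf3D <- function() {
  c("ethanol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    1.2304   -0.2164    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.4562    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.1000   -0.3351    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$")
}

# Small cached benchmark so several test files reuse one generation pass.
smallBenchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeBenchmark(6, seed = 3181, nResidues = 20,
                                                pocketSize = 4, nDecoys = 4)
    cache
  }
})

# A small trained residue model shared between model tests (kept tiny so the
# whole suite stays fast).
tinyTrainedModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- trainResidueModel(smallBenchmark(),
                                  modelConfig(2, 16, seed = 5),
                                  epochs = 4, nDecoys = 3, seed = 9)
    cache
  }
})

expectSetEqual <- function(a, b) testthat::expect_setequal(a, b)
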