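# Independent brute-force greedy oracle over an injected coverage table.
oracleGreedy <- function(coverage, trueSets, threshold, batch) {
  covered <- lapply(batch, function(p) integer(0))
  names(covered) <- batch
  selected <- character(0)
  pool <- sort(unique(unlist(lapply(coverage, names))))
  meanRec <- function() mean(vapply(batch, function(p)
    length(intersect(covered[[p]], trueSets[[p]])) / length(trueSets[[p]]),
    numeric(1)))
  repeat {
    if (meanRec() > threshold) break
    best <- NULL; bestGain <- 0
    for (lig in pool) {
      if (lig %in% selected) next
      gain <- 0
      for (p in batch) {
        s <- coverage[[p]][[lig]]
        if (is.null(s)) s <- integer(0)
        gain <- gain + length(setdiff(intersect(s, trueSets[[p]]),
                                      covered[[p]]))
      }
      if (gain > bestGain) { bestGain <- gain; best <- lig }
    }
    if (is.null(best)) break
    selected <- c(selected, best)
    for (p in batch) {
      s <- coverage[[p]][[best]]
      if (!is.null(s))
        covered[[p]] <- union(covered[[p]], intersect(s, trueSets[[p]]))
    }
  }
  selected
}

randomCoverage <- function(nProt, nLig, nRes = 12) {
  prots <- paste0("P", seq_len(nProt))
  ligs <- paste0("L", sprintf("%02d", seq_len(nLig)))
  coverage <- setNames(lapply(prots, function(p)
    setNames(lapply(ligs, function(l)
      sort(sample.int(nRes, sample(0:6, 1)))), ligs)), prots)
  trueSets <- setNames(lapply(prots, function(p)
    sort(sample.int(nRes, sample(3:6, 1)))), prots)
  list(coverage = coverage, trueSets = trueSets)
}

test_that("predictedCover thresholds probabilities inclusively", {
  expect_equal(predictedCover(c(0.6, 0.4, 0.5)), c(1L, 3L))
  expect_equal(predictedCover(c(0.6, 0.4, 0.5), threshold = 1.1), integer(0))
})

test_that("recall is the covered fraction of the true set", {
  expect_equal(pocketRecall(1:10, 3:5), 1.0)
  expect_equal(pocketRecall(1:2, 5:8), 0.0)
  expect_equal(pocketRecall(c(1, 2, 3, 9), 1:4), 0.75)
  expect_error(pocketRecall(1:3, integer(0)), "empty")
})

test_that("greedy selection equals the brute-force oracle on random tables", {
  withr::with_seed(53, {
    for (rep in 1:8) {
      tc <- randomCoverage(sample(4:10, 1), sample(6:20, 1))
      got <- greedySelect(tc$coverage, tc$trueSets, coverageThreshold = 0.8,
                          batchSize = 100)
      want <- oracleGreedy(tc$coverage, tc$trueSets, 0.8,
                           names(tc$coverage))
      expect_identical(got$probes, want)
    }
  })
})

test_that("one all-covering ligand gives a singleton probe set", {
  coverage <- list(P1 = list(A = 1:5, B = 1L), P2 = list(A = 1:5, B = 2L))
  trueSets <- list(P1 = c(1L, 3L), P2 = c(2L, 5L))
  sel <- greedySelect(coverage, trueSets)
  expect_identical(sel$probes, "A")
  expect_equal(unname(sel$recall), c(1, 1))
})

test_that("a batch already above the threshold contributes no new probes", {
  # batch 1 forces selection of A; batch 2 is fully covered by A already
  coverage <- list(P1 = list(A = 1:4, B = 1:2),
                   P2 = list(A = 1:4, B = 1:4))
  trueSets <- list(P1 = 1:4, P2 = 1:4)
  sel <- greedySelect(coverage, trueSets, coverageThreshold = 0.8,
                      batchSize = 1)
  expect_identical(sel$probes, "A")
})

test_that("ties break to the lexicographically smaller ligand id", {
  coverage <- list(P1 = list(Lb = 1:3, La = 1:3))
  trueSets <- list(P1 = 1:3)
  sel <- greedySelect(coverage, trueSets)
  expect_identical(sel$probes, "La")
})

test_that("every selected probe adds strictly positive coverage", {
  withr::with_seed(59, {
    tc <- randomCoverage(6, 12)
    sel <- greedySelect(tc$coverage, tc$trueSets, batchSize = 3)
    covered <- lapply(names(tc$coverage), function(p) integer(0))
    names(covered) <- names(tc$coverage)
    for (lig in sel$probes) {
      gain <- 0
      for (p in names(covered)) {
        s <- tc$coverage[[p]][[lig]]
        gain <- gain + length(setdiff(intersect(s, tc$trueSets[[p]]),
                                      covered[[p]]))
        covered[[p]] <- union(covered[[p]],
                              intersect(s, tc$trueSets[[p]]))
      }
      expect_gt(gain, 0)
    }
  })
})

test_that("proteins with empty true sets are excluded with a warning", {
  coverage <- list(P1 = list(A = 1:3), P2 = list(A = 1:3))
  trueSets <- list(P1 = 1:3, P2 = integer(0))
  expect_warning(sel <- greedySelect(coverage, trueSets), "empty true")
  expect_equal(names(sel$recall), "P1")
})

test_that("coverage curves are monotone in the prefix and match recomputation", {
  withr::with_seed(61, {
    tc <- randomCoverage(5, 8)
    sel <- greedySelect(tc$coverage, tc$trueSets, coverageThreshold = 0.99)
    if (length(sel$probes) >= 2) {
      curve <- coverageCurve(sel$probes, tc$coverage, tc$trueSets)
      for (th in unique(curve$threshold)) {
        fr <- curve$fraction[curve$threshold == th]
        expect_true(all(diff(fr) >= 0))
      }
      # direct recomputation for the full prefix
      full <- curve[curve$prefix == length(sel$probes), ]
      rec <- vapply(names(tc$coverage), function(p) {
        cov <- unique(unlist(tc$coverage[[p]][sel$probes]))
        pocketRecall(intersect(cov, tc$trueSets[[p]]), tc$trueSets[[p]])
      }, numeric(1))
      for (i in seq_len(nrow(full)))
        expect_equal(full$fraction[i], mean(rec > full$threshold[i]))
    }
  })
})

test_that("a full-coverage predictor saturates the curve below recall 1", {
  coverage <- list(P1 = list(A = 1:4), P2 = list(A = 1:6))
  trueSets <- list(P1 = 1:4, P2 = 1:6)
  curve <- coverageCurve("A", coverage, trueSets,
                         thresholds = c(0, 0.5, 0.99))
  expect_true(all(curve$fraction == 1))
})

test_that("empty pools and empty protein lists return empty probe sets", {
  expect_identical(greedySelect(list(), list())$probes, character(0))
})
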