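test_that("ground truths are reproducible, acyclic and sized as asked", {
  t1 <- makeTruth(seed = 4)
  t2 <- makeTruth(seed = 4)
  expect_identical(edges(t1), edges(t2))
  expect_identical(nrow(edges(t1)), 6L)

  # fixed cascade: two 3-type chains plus two isolated interactions
  expect_identical(unname(edges(t1)),
                   cbind(c("CT01", "CT02", "CT04", "CT05", "CT07", "CT09"),
                         c("CT02", "CT03", "CT05", "CT06", "CT08", "CT10")))

  t0 <- makeTruth(nEdges = 0)
  expect_identical(nrow(edges(t0)), 0L)

  for (sd in 1:50) {
    tr <- makeTruth(nTypes = 6, nEdges = sample(0:5, 1), seed = sd,
                    topology = "random")
    expect_s4_class(tr@model@dag, "Dag")  # validity enforces acyclicity
  }
  # denser-than-forest random DAGs still come out acyclic
  for (sd in 1:20) {
    tr <- makeTruth(nTypes = 5, nEdges = 8, seed = sd,
                    topology = "random", nGenes = 100)
    expect_s4_class(tr@model@dag, "Dag")
  }
  expect_error(makeTruth(nTypes = 4, nEdges = 7, topology = "random"),
               "exceeds")
  expect_error(makeTruth(dropout = 1), "dropout")
})

test_that("ancestral sampling matches the CPT-implied joint", {
  # 2-node chain with flip 0.1: joint computable in closed form
  truth <- makeTruth(nTypes = 4, nEdges = 1, seed = 2, nBackground = 0, weakEdgeFlip = 0.1)
  S <- sampleStates(truth@model, 4000, seed = 3)
  parent <- edges(truth)[1, 1]; child <- edges(truth)[1, 2]
  expect_equal(mean(S[, parent]), 0.5, tolerance = 0.05)
  expect_equal(mean(S[, child] == S[, parent]), 0.9, tolerance = 0.03)
  # independent roots stay near their 0.5 marginal and uncorrelated
  roots <- setdiff(colnames(S), c(parent, child))
  expect_equal(unname(colMeans(S[, roots])), c(0.5, 0.5),
               tolerance = 0.05)
  expect_lt(abs(cor(S[, roots[1]], S[, roots[2]])), 0.05)
})

test_that("simulated expression follows the marker model", {
  truth <- makeTruth(nTypes = 4, nEdges = 1, seed = 5, nBackground = 2,
                     backgroundWeight = 0.5, markerExpr = 2,
                     baselineExpr = 0.2)
  sce <- simulateDataset(truth, nSamples = 6, cellsPerSample = 400,
                         seed = 6)
  cells <- which(sce$true_type == "CT01")
  m <- as.matrix(SummarizedExperiment::assay(sce)[, cells])
  mk <- truth@markers[["CT01"]]
  se <- sqrt(2 / (length(cells) * length(mk)))
  expect_lt(abs(mean(m[mk, ]) - 2), 3 * se)
  bg <- setdiff(rownames(m), unlist(truth@markers))
  expect_lt(abs(mean(m[bg, ]) - 0.2), 0.05)
  # annotation recovers the generating type nearly perfectly at dropout 0
  expect_gt(mean(sce$cell_type == sce$true_type), 0.95)

  # per-sample composition counts honour the multinomial draw exactly
  expect_true(all(table(sce$sample_id) == 400))
})

test_that("dropout zeroes counts at the requested rate", {
  t0 <- makeTruth(nTypes = 3, nEdges = 0, seed = 7, nBackground = 0,
                  markerExpr = 5, baselineExpr = 1)
  t5 <- t0; t5@dropout <- 0.5
  s0 <- simulateDataset(t0, nSamples = 4, cellsPerSample = 300, seed = 8)
  s5 <- simulateDataset(t5, nSamples = 4, cellsPerSample = 300, seed = 8)
  m0 <- SummarizedExperiment::assay(s0)
  m5 <- SummarizedExperiment::assay(s5)
  kept <- sum(m5 > 0) / sum(m0 > 0)
  expect_equal(kept, 0.5, tolerance = 0.03)
})

test_that("recovery scoring implements the stated definitions", {
  truth <- makeTruth(seed = 1)   # 6 cascade edges
  types <- c(cellTypes(truth), "BG01")
  # 5 of 6 true edges found, nothing else
  found <- edges(truth)[1:5, , drop = FALSE]
  cnt <- setNames(as.list(rep(30, 5)),
                  paste0(found[, 1], "->", found[, 2]))
  ect <- makeCountTable(types, cnt)
  ev <- evaluateRecovery(ect, truth, threshold = 20)
  expect_equal(ev$accuracy, 5 / 6, tolerance = 1e-12)
  expect_equal(ev$precision, 1)
  expect_identical(ev$fp, 0L)

  # 4 of 6, with a reversed direction still matched undirected
  rev4 <- cbind(edges(truth)[1:4, 2], edges(truth)[1:4, 1])
  cnt4 <- setNames(as.list(rep(25, 4)),
                   paste0(rev4[, 1], "->", rev4[, 2]))
  ev4 <- evaluateRecovery(makeCountTable(types, cnt4), truth, 20)
  expect_equal(ev4$accuracy, 4 / 6, tolerance = 1e-12)
  expect_equal(ev4$precision, 1)
  # ... but not when direction-sensitive
  evd <- evaluateRecovery(makeCountTable(types, cnt4), truth, 20,
                          directionSensitive = TRUE)
  expect_identical(evd$tp, 0L)

  # empty prediction: accuracy 0, precision 1 by convention, flagged
  ev0 <- evaluateRecovery(makeCountTable(types, list()), truth, 20)
  expect_identical(ev0$accuracy, 0)
  expect_identical(ev0$precision, 1)
  expect_true(ev0$flagged)
})

test_that("the dropout sweep reports one row per rate and decays", {
  truth <- makeTruth(nTypes = 4, nEdges = 2, seed = 3, nBackground = 2, weakEdgeFlip = 0.1,
                     backgroundWeight = 0.5)
  tab <- dropoutSweep(truth, rates = c(0, 0.9), seed = 4, nSamples = 15,
                      cellsPerSample = 250, nIter = 8, threshold = 2,
                      minCells = 30)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$rate, c(0, 0.9))

  # trend over seeds: extreme dropout never helps (median comparison)
  acc <- sapply(1:5, function(s) {
    tb <- dropoutSweep(truth, rates = c(0, 0.9), seed = 10 + s,
                       nSamples = 15, cellsPerSample = 250, nIter = 8,
                       threshold = 2, minCells = 30)
    tb$accuracy
  })
  expect_gte(median(acc[1, ]), median(acc[2, ]))
})

test_that("simulated datasets round-trip through the io layer", {
  truth <- makeTruth(nTypes = 3, nEdges = 1, seed = 9, nBackground = 1, weakEdgeFlip = 0.1,
                     backgroundWeight = 0.5)
  sce <- simulateCaseControl(truth, nSamples = 3, cellsPerSample = 100,
                             seed = 10)
  expect_setequal(unique(sce$condition), c("control", "case"))
  d <- tempfile()
  writeExpression(sce, d)
  writeTruth(truth, d)
  back <- loadExpression(file.path(d, "matrix.mtx"),
                         file.path(d, "cells.tsv"),
                         file.path(d, "genes.tsv"))
  expect_equal(dim(back), dim(sce))
  expect_identical(back$cell_type, sce$cell_type)
  te <- read.delim(file.path(d, "truth_edges.tsv"), comment.char = "#")
  expect_identical(nrow(te), 1L)
})
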