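test_that("condition log fold changes follow the closed form", {
  counts <- cbind(matrix(3, 2, 4), matrix(1, 2, 4))
  sce <- makeTinySCE(counts, sample_id = rep("s1", 8),
                     condition = rep(c("case", "ctrl"), each = 4),
                     cell_type = rep("T", 8))
  lfc <- conditionLFC(sce, "T", "case", "ctrl", pseudocount = 1)
  expect_equal(unname(lfc), rep(log(2), 2))
  expect_equal(unname(conditionLFC(sce, "T", "case", "case")), c(0, 0))
  expect_error(conditionLFC(sce, "B", "case", "ctrl"), "absent")

  # doubling case-side expression raises every gene's lfc
  sce2 <- sce
  i <- sce2$condition == "case"
  SummarizedExperiment::assay(sce2)[, i] <-
    2 * SummarizedExperiment::assay(sce2)[, i]
  expect_true(all(conditionLFC(sce2, "T", "case", "ctrl") > lfc))
})

test_that("design folding is exact", {
  I <- diag(2)
  dimnames(I) <- list(c("t1", "t2"), c("l1", "l2"))
  A <- buildDesign(newLigandTargetMatrix(I), c(l1 = 2, l2 = 3))
  expect_equal(unname(A), diag(c(2, 3)))
  expect_equal(unname(buildDesign(newLigandTargetMatrix(I),
                                  c(l1 = 0, l2 = 0))),
               matrix(0, 2, 2))

  set.seed(1)
  I2 <- matrix(runif(20), 5, 4,
               dimnames = list(paste0("t", 1:5), paste0("l", 1:4)))
  L <- setNames(rnorm(4), paste0("l", 1:4))
  A2 <- buildDesign(newLigandTargetMatrix(I2), L)
  for (t in 1:5) for (l in 1:4)
    expect_equal(A2[t, l], I2[t, l] * L[[l]])

  expect_warning(
    Adrop <- buildDesign(newLigandTargetMatrix(I2), L[1:3]), "dropped")
  expect_identical(ncol(Adrop), 3L)
  expect_error(buildDesign(newLigandTargetMatrix(I2),
                           c(x = 1)), "no ligand")
})

test_that("the LASSO recovers a sparse planted activity vector", {
  set.seed(2)
  nT <- 200; nL <- 20
  A <- matrix(runif(nT * nL), nT, nL,
              dimnames = list(sprintf("t%03d", 1:nT),
                              sprintf("l%02d", 1:nL)))
  alphaStar <- setNames(numeric(nL), colnames(A))
  alphaStar[c("l03", "l11", "l17")] <- c(2, -1.5, 1)
  Tv <- setNames(as.numeric(A %*% alphaStar), rownames(A))
  fit <- fitLTR(A, Tv, nFolds = 5, seed = 3)
  expect_false(isDegenerate(fit))
  expect_gte(meanPearson(fit), 0.99)
  for (f in fit@folds) {
    expect_true(all(abs(f$alpha[c("l03", "l11", "l17")]) > 0.1))
    # shared-coefficient contract: one alpha per ligand for every target
    expect_length(f$alpha, nL)
  }

  # response unrelated to the design: held-out correlation near zero
  ps <- vapply(1:5, function(s) {
    shuffled <- setNames(sample(Tv), names(Tv))
    mp <- meanPearson(fitLTR(A, shuffled, seed = s))
    if (is.na(mp)) 0 else mp
  }, numeric(1))
  expect_lt(abs(mean(ps)), 0.15)

  expect_error(fitLTR(A[1:3, ], Tv[1:3], nFolds = 5), "fewer targets")
})

test_that("ligand ranking is the mean lfc-activity product", {
  fit <- new("LtrFit",
             folds = list(list(alpha = c(l1 = 1, l2 = 0), lambda = 0.1,
                               pearson = 0.9, bias = 0, mse = 0.1)),
             meanPearson = 0.9, degenerate = FALSE)
  rk <- rankLigands(fit, c(l1 = 2, l2 = 5))
  expect_identical(rk$ligand, c("l1", "l2"))
  expect_equal(rk$score, c(2, 0))

  # negative lfc with positive activity: negative score, ranked by size
  fit2 <- new("LtrFit",
              folds = rep(list(list(alpha = c(l1 = 1, l2 = 0.1),
                                    lambda = 0.1, pearson = 0.9,
                                    bias = 0, mse = 0.1)), 3),
              meanPearson = 0.9, degenerate = FALSE)
  rk2 <- rankLigands(fit2, c(l1 = -2, l2 = 1))
  expect_equal(rk2$score[rk2$ligand == "l1"], -2)
  expect_identical(rk2$ligand[1], "l1")

  deg <- new("LtrFit", folds = list(), meanPearson = NA_real_,
             degenerate = TRUE)
  rkd <- rankLigands(deg, c(l1 = 1))
  expect_identical(nrow(rkd), 0L)
  expect_true(attr(rkd, "degenerate"))
})

test_that("activity scales inversely with the ligand vector (product invariant)", {
  set.seed(4)
  nT <- 120; nL <- 10
  I <- matrix(runif(nT * nL), nT, nL,
              dimnames = list(sprintf("t%03d", 1:nT),
                              sprintf("l%02d", 1:nL)))
  L <- setNames(runif(nL, 0.5, 2), colnames(I))
  alphaStar <- setNames(c(3, -2, rep(0, nL - 2)), colnames(I))
  Tv <- setNames(as.numeric(sweep(I, 2, L, "*") %*% alphaStar),
                 rownames(I))
  f1 <- fitLTR(buildDesign(newLigandTargetMatrix(I), L), Tv, seed = 5)
  f2 <- fitLTR(buildDesign(newLigandTargetMatrix(I), 3 * L), Tv, seed = 5)
  s1 <- rankLigands(f1, L)
  s2 <- rankLigands(f2, 3 * L)
  m <- match(s1$ligand, s2$ligand)
  expect_equal(s1$score, s2$score[m], tolerance = 0.05)
})

test_that("paracrine fit beats the autocrine control on planted signal", {
  toy <- makeLtrToy(seed = 6)
  para <- ltrForPair(toy$sce, toy$ltm, "sender", "receiver",
                     "case", "ctrl", seed = 7)
  auto <- autocrineControl(toy$sce, toy$ltm, "receiver", "case", "ctrl",
                           seed = 7)
  expect_false(isDegenerate(para))
  expect_gt(meanPearson(para), 0.5)
  autoScore <- if (isDegenerate(auto) || is.na(meanPearson(auto))) -Inf
               else meanPearson(auto)
  expect_gt(meanPearson(para), autoScore)
  # ranked ligands put the planted ones on top
  rk <- attr(para, "ranking")
  expect_true(all(toy$active %in% rk$ligand[seq_len(5)]))
})

test_that("shuffling the interaction matrix destroys the fit", {
  toy <- makeLtrToy(seed = 8)
  para <- ltrForPair(toy$sce, toy$ltm, "sender", "receiver",
                     "case", "ctrl", seed = 9)
  L <- attr(para, "L")
  Tv <- conditionLFC(toy$sce, "receiver", "case", "ctrl")[attr(para,
                                                               "targets")]
  I <- potentials(toy$ltm)[attr(para, "targets"), , drop = FALSE]
  ctrl <- randomMatrixControl(newLigandTargetMatrix(I), Tv, L,
                              nShuffles = 10, seed = 10)
  expect_false(isDegenerate(para))
  realP <- meanPearson(para)
  shufP <- ctrl$pearsons
  expect_true(ctrl$fracDegenerate >= 0.5 ||
                all(shufP < realP - 0.2))

  # shuffling a constant matrix is a no-op
  Ic <- matrix(1, 10, 4, dimnames = list(sprintf("t%d", 1:10),
                                         sprintf("l%d", 1:4)))
  Lc <- setNames(rep(1, 4), colnames(Ic))
  Tc <- setNames(rnorm(10), rownames(Ic))
  direct <- fitLTR(buildDesign(newLigandTargetMatrix(Ic), Lc), Tc,
                   nFolds = 2, seed = 11)
  noop <- randomMatrixControl(newLigandTargetMatrix(Ic), Tc, Lc,
                              nShuffles = 1, nFolds = 2, seed = 11)
  expect_equal(meanPearson(noop$fits[[1]]), meanPearson(direct))

  r1 <- randomMatrixControl(newLigandTargetMatrix(I), Tv, L,
                            nShuffles = 2, seed = 12)
  r2 <- randomMatrixControl(newLigandTargetMatrix(I), Tv, L,
                            nShuffles = 2, seed = 12)
  expect_equal(vapply(r1$fits, meanPearson, numeric(1)),
               vapply(r2$fits, meanPearson, numeric(1)))
})

test_that("joint agreement of edge counts and fit quality", {
  mkfit <- function(p) new("LtrFit",
                           folds = list(list(alpha = c(l1 = 1),
                                             lambda = 1, pearson = p,
                                             bias = 0, mse = 1 - p)),
                           meanPearson = p, degenerate = FALSE)
  pairs <- data.frame(from = c("A", "B", "C", "D"),
                      to = c("B", "C", "D", "A"),
                      count = c(25, 40, 60, 90))
  # y exactly linear in log(count): r = 1
  fits <- setNames(lapply(log(pairs$count) / 10, mkfit),
                   paste(pairs$from, "->", pairs$to))
  res <- bnLtrAgreement(pairs, fits, threshold = 20)
  expect_equal(res$r, 1, tolerance = 1e-12)

  # constant y: undefined, flagged
  fitsC <- setNames(lapply(rep(0.5, 4), mkfit),
                    paste(pairs$from, "->", pairs$to))
  resC <- bnLtrAgreement(pairs, fitsC, threshold = 20)
  expect_true(is.na(resC$r))
  expect_match(resC$flag, "variance")

  # fewer than 3 retained pairs: flagged
  res2 <- bnLtrAgreement(pairs[1:2, ], fits[1:2], threshold = 20)
  expect_match(res2$flag, "fewer than 3")

  # r matches the closed-form correlation on random data
  set.seed(13)
  n <- 50
  cnt <- sample(21:99, n, replace = TRUE)
  ys <- runif(n)
  prs <- data.frame(from = sprintf("x%d", 1:n), to = sprintf("y%d", 1:n),
                    count = cnt)
  fitsR <- setNames(lapply(ys, mkfit), paste(prs$from, "->", prs$to))
  resR <- bnLtrAgreement(prs, fitsR, threshold = 20)
  x <- log(cnt)
  manual <- sum((x - mean(x)) * (ys - mean(ys))) /
    sqrt(sum((x - mean(x))^2) * sum((ys - mean(ys))^2))
  expect_equal(resR$r, manual, tolerance = 1e-12)
})
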