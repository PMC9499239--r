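# Ligand-target regression (LTR): a LASSO with one shared activity
# coefficient per ligand. For a directed cell type pair A -> B the design
# folds a ligand-target regulatory potential matrix I through the observed
# ligand expression change L in the sender: A[t, l] = I[t, l] * L[l]; the
# response is the expression change of target genes in the receiver. The
# same per-ligand activity applies to every target, so held-out targets
# are predictable and the fit can be cross-validated target-wise.

#' Per-gene log expression change of a cell type between conditions
#'
#' For every gene, `log((mean in condA cells of the type + pc) / (mean in
#' condB cells of the type + pc))`, natural log, means over raw counts.
#'
#' @param sce a `SingleCellExperiment` with `condition` and `cell_type`
#'   in its `colData`.
#' @param cellType the cell type whose cells are averaged.
#' @param condA,condB numerator and denominator conditions.
#' @param pseudocount positive stabilizer added to both means (default 1).
#' @return named numeric vector over the genes of `sce`.
#' @export
conditionLFC <- function(sce, cellType, condA, condB, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  cd <- SummarizedExperiment::colData(sce)
  ia <- cd$cell_type == cellType & cd$condition == condA
  ib <- cd$cell_type == cellType & cd$condition == condB
  if (!any(ia) || !any(ib))
    stop("cell type '", cellType, "' is absent from condition '",
         if (!any(ia)) condA else condB, "'")
  m <- SummarizedExperiment::assay(sce, "counts")
  ma <- Matrix::rowMeans(m[, ia, drop = FALSE])
  mb <- Matrix::rowMeans(m[, ib, drop = FALSE])
  setNames(log((ma + pseudocount) / (mb + pseudocount)), rownames(sce))
}

#' Fold ligand expression into the LTR design matrix
#'
#' `A[t, l] = I[t, l] * L[l]` over the ligands shared between the
#' potential matrix and the expression vector; potential-matrix ligands
#' without an expression value are dropped with a warning.
#'
#' @param ltm a [LigandTargetMatrix-class].
#' @param L named numeric vector of ligand expression (log) changes.
#' @return numeric design matrix, targets x retained ligands.
#' @export
buildDesign <- function(ltm, L) {
  I <- ltm@potential
  common <- intersect(colnames(I), names(L))
  if (!length(common))
    stop("no ligand of the potential matrix has an expression value")
  dropped <- setdiff(colnames(I), common)
  if (length(dropped))
    warning(length(dropped),
            " ligand(s) without expression dropped from the design")
  sweep(I[, common, drop = FALSE], 2L, L[common], "*")
}

#' Fit the ligand-target regression by cross-validated LASSO
#'
#' Targets (rows of the design) are partitioned into `nFolds` folds. For
#' each fold, the penalty is selected on a single 50/50 split of the
#' training rows over a 100-point grid descending four decades from the
#' smallest all-zero penalty; the model is then refit on all training rows
#' at the selected penalty and the held-out targets are predicted as
#' `A alpha + bias`. Columns are not standardized, so coefficients remain
#' interpretable as ligand activities on the regulatory-potential scale. A
#' fold whose coefficients are all zero contributes no correlation; a fit
#' in which every fold is all-zero is flagged `degenerate` and carries no
#' mean correlation at all.
#'
#' @param A design matrix from [buildDesign()] (targets x ligands, at
#'   least two ligands).
#' @param Tvec named numeric response: expression change of each target in
#'   the receiver; names must match `rownames(A)`.
#' @param nFolds number of folds (default 5); there must be at least
#'   `nFolds` targets.
#' @param seed integer seed driving the fold partition and the 50/50
#'   split.
#' @return an [LtrFit-class].
#' @export
fitLTR <- function(A, Tvec, nFolds = 5L, seed = 1L) {
  if (is.null(names(Tvec))) names(Tvec) <- rownames(A)
  A <- A[names(Tvec), , drop = FALSE]
  n <- nrow(A)
  if (n < nFolds) stop("fewer targets (", n, ") than folds (", nFolds, ")")
  if (ncol(A) < 2L) stop("need at least two ligands")
  old <- .safeSetSeed(seed)
  foldId <- sample(rep_len(seq_len(nFolds), n))
  splitDraw <- runif(n)
  .restoreSeed(old)
  folds <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    test <- foldId == f
    train <- !test
    lam <- .selectLambda(A[train, , drop = FALSE], Tvec[train],
                         splitDraw[train])
    fit <- .lassoAt(A[train, , drop = FALSE], Tvec[train], lam)
    pred <- as.numeric(A[test, , drop = FALSE] %*% fit$alpha + fit$bias)
    pearson <- if (sd(pred) > 0 && sd(Tvec[test]) > 0)
      cor(pred, Tvec[test]) else NA_real_
    folds[[f]] <- list(alpha = fit$alpha, bias = fit$bias, lambda = lam,
                       pearson = pearson,
                       mse = mean((pred - Tvec[test])^2))
  }
  zero <- vapply(folds, function(f) all(f$alpha == 0), logical(1))
  degenerate <- all(zero)
  ps <- vapply(folds, `[[`, numeric(1), "pearson")[!zero]
  mp <- if (degenerate || all(is.na(ps))) NA_real_ else mean(ps, na.rm = TRUE)
  new("LtrFit", folds = folds, meanPearson = mp, degenerate = degenerate)
}

# lambda by validation on a 50/50 split of the training targets; the grid
# spans 4 decades below the smallest penalty that zeroes all coefficients.
# The largest lambda within one standard error of the minimum validation
# MSE is selected (the usual conservative rule): with an uninformative
# design the chance dips of the validation curve stay within one SE of
# the all-zero model, which is then correctly preferred.
.selectLambda <- function(A, y, draw) {
  half1 <- draw < stats::median(draw)
  if (sum(half1) < 2L || sum(!half1) < 1L)
    half1 <- seq_along(y) <= ceiling(length(y) / 2)
  lamMax <- max(abs(crossprod(A[half1, , drop = FALSE],
                              y[half1] - mean(y[half1])))) / sum(half1)
  if (!is.finite(lamMax) || lamMax <= 0) return(Inf)
  grid <- exp(seq(log(lamMax), log(lamMax * 1e-4), length.out = 100L))
  fit <- tryCatch(
    glmnet::glmnet(A[half1, , drop = FALSE], y[half1], lambda = grid,
                   standardize = FALSE, intercept = TRUE),
    error = function(e) NULL)    # e.g. all predictors constant
  if (is.null(fit)) return(Inf)
  pred <- predict(fit, A[!half1, , drop = FALSE])
  err2 <- (pred - y[!half1])^2
  mse <- colMeans(err2)
  k <- which.min(mse)
  se <- stats::sd(err2[, k]) / sqrt(nrow(err2))
  lam <- max(grid[mse <= mse[k] + se])
  # the boundary of the grid is the all-zero model: selecting it means
  # the null model won, which must carry over to the full-fold refit
  # (whose own all-zero penalty can be larger than the split's)
  if (lam >= grid[[1L]]) Inf else lam
}

.lassoAt <- function(A, y, lam) {
  if (!is.finite(lam))
    return(list(alpha = setNames(numeric(ncol(A)), colnames(A)),
                bias = mean(y)))
  # refit on the descending path down to lam so the coordinate descent is
  # warm-started, then read coefficients at lam
  grid <- exp(seq(log(max(lam * 1e4,
                          max(abs(crossprod(A, y - mean(y)))) / nrow(A))),
                  log(lam), length.out = 60L))
  fit <- tryCatch(
    glmnet::glmnet(A, y, lambda = grid, standardize = FALSE,
                   intercept = TRUE),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(alpha = setNames(numeric(ncol(A)), colnames(A)),
                bias = mean(y)))
  cf <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  list(alpha = setNames(cf[-1L], colnames(A)), bias = cf[[1L]])
}

#' Rank ligands of a fitted LTR model
#'
#' Score of ligand l is the mean over folds of `L[l] * alpha_fold[l]` (log
#' fold change times fitted activity), ranked by absolute score. A
#' degenerate fit yields an empty ranking flagged via the `degenerate`
#' attribute.
#'
#' @param fit an [LtrFit-class].
#' @param L the ligand expression change vector used in the design.
#' @return data.frame with columns `ligand`, `score`, `lfc`,
#'   `mean_alpha`, sorted by `|score|` descending.
#' @export
rankLigands <- function(fit, L) {
  if (fit@degenerate) {
    out <- data.frame(ligand = character(0), score = numeric(0),
                      lfc = numeric(0), mean_alpha = numeric(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  am <- do.call(rbind, lapply(fit@folds, `[[`, "alpha"))
  lig <- colnames(am)
  meanAlpha <- colMeans(am)
  score <- vapply(lig, function(l) mean(L[[l]] * am[, l]), numeric(1))
  out <- data.frame(ligand = lig, score = score, lfc = L[lig],
                    mean_alpha = meanAlpha)
  out <- out[order(-abs(out$score), out$ligand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  out
}

#' Run the LTR pipeline for one directed cell type pair
#'
#' Computes the sender's ligand expression changes and the receiver's
#' target expression changes with [conditionLFC()], folds the potential
#' matrix into the design and fits the cross-validated LASSO. The target
#' universe is the genes present in both the potential matrix and the
#' dataset, excluding the ligand genes themselves (no leakage of the
#' predictors into the response).
#'
#' @param sce the annotated expression dataset.
#' @param ltm a [LigandTargetMatrix-class].
#' @param sender,receiver cell types with the outgoing and incoming edge.
#' @param condA,condB conditions contrasted (case, control).
#' @param mode `"lfc"` (default) uses log fold changes for both ligand and
#'   target vectors; `"levels"` uses `log(mean + pc)` ligand levels and
#'   raw mean target levels in `condA` only.
#' @param pseudocount,nFolds,seed as in [conditionLFC()] and [fitLTR()].
#' @return an [LtrFit-class] with attributes `L` (ligand vector),
#'   `targets` and `ranking` (the [rankLigands()] table).
#' @export
ltrForPair <- function(sce, ltm, sender, receiver, condA, condB,
                       mode = c("lfc", "levels"), pseudocount = 1,
                       nFolds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  ligGenes <- intersect(ligands(ltm), rownames(sce))
  if (!length(ligGenes)) stop("no ligand of the matrix is in the dataset")
  tgGenes <- setdiff(intersect(targets(ltm), rownames(sce)), ligGenes)
  if (!length(tgGenes)) stop("no usable target gene")
  if (mode == "lfc") {
    L <- conditionLFC(sce, sender, condA, condB, pseudocount)[ligGenes]
    Tv <- conditionLFC(sce, receiver, condA, condB, pseudocount)[tgGenes]
  } else {
    L <- log(.typeMeans(sce, sender, condA) + pseudocount)[ligGenes]
    Tv <- .typeMeans(sce, receiver, condA)[tgGenes]
  }
  I <- ltm@potential[tgGenes, , drop = FALSE]
  A <- buildDesign(newLigandTargetMatrix(I), L)
  fit <- fitLTR(A, Tv, nFolds = nFolds, seed = seed)
  attr(fit, "L") <- L
  attr(fit, "targets") <- tgGenes
  attr(fit, "ranking") <- rankLigands(fit, L)
  fit
}

.typeMeans <- function(sce, cellType, cond) {
  cd <- SummarizedExperiment::colData(sce)
  i <- cd$cell_type == cellType & cd$condition == cond
  if (!any(i))
    stop("cell type '", cellType, "' is absent from condition '", cond, "'")
  m <- SummarizedExperiment::assay(sce, "counts")
  setNames(Matrix::rowMeans(m[, i, drop = FALSE]), rownames(sce))
}

#' Autocrine control fit
#'
#' The same pipeline as [ltrForPair()] with the receiver's own ligands as
#' predictors (`sender := receiver`). A genuine paracrine interaction
#' should beat this control in held-out correlation.
#'
#' @inheritParams ltrForPair
#' @export
autocrineControl <- function(sce, ltm, receiver, condA, condB,
                             mode = "lfc", pseudocount = 1, nFolds = 5L,
                             seed = 1L)
  ltrForPair(sce, ltm, receiver, receiver, condA, condB, mode = mode,
             pseudocount = pseudocount, nFolds = nFolds, seed = seed)

#' Shuffled interaction-matrix control
#'
#' Refits the LTR after randomly permuting all entries of the potential
#' matrix (breaking the ligand-target assignments), `nShuffles` times.
#' With an informative matrix most shuffled fits collapse to the all-zero
#' solution.
#'
#' @param ltm a [LigandTargetMatrix-class].
#' @param Tvec,L response and ligand vectors as in [fitLTR()] /
#'   [buildDesign()].
#' @param nShuffles number of shuffles (default 20).
#' @param nFolds,seed as in [fitLTR()].
#' @return list with `fits`, `fracDegenerate` and `pearsons` (mean
#'   held-out correlation per non-degenerate shuffle).
#' @export
randomMatrixControl <- function(ltm, Tvec, L, nShuffles = 20L, nFolds = 5L,
                                seed = 1L) {
  I <- ltm@potential[names(Tvec), , drop = FALSE]
  fits <- vector("list", nShuffles)
  for (s in seq_len(nShuffles)) {
    old <- .safeSetSeed(.deriveSeed(seed, s))
    Iperm <- matrix(sample(I), nrow(I), ncol(I), dimnames = dimnames(I))
    .restoreSeed(old)
    common <- intersect(colnames(Iperm), names(L))
    A <- sweep(Iperm[, common, drop = FALSE], 2L, L[common], "*")
    fits[[s]] <- fitLTR(A, Tvec, nFolds = nFolds,
                        seed = .deriveSeed(seed, 1000L + s))
  }
  deg <- vapply(fits, isDegenerate, logical(1))
  ps <- vapply(fits, meanPearson, numeric(1))
  list(fits = fits, fracDegenerate = mean(deg), pearsons = ps[!deg])
}

#' Agreement between bootstrap edge scores and LTR correlations
#'
#' Joint view of the two evidence channels: for each retained cell type
#' pair, x is the log bootstrap edge count and y the mean held-out LTR
#' correlation; the returned statistic is the Pearson correlation between
#' x and y. Pairs below the count threshold and degenerate fits are
#' dropped; with fewer than 3 retained pairs, or zero variance on either
#' axis, the correlation is undefined and flagged.
#'
#' @param pairs data.frame with columns `from`, `to`, `count`.
#' @param fits named list of [LtrFit-class] objects, names
#'   `"from -> to"`.
#' @param threshold minimum edge count (default 20).
#' @param statistic `"pearson"` (default) or `"mse"`: with `"mse"` the
#'   y axis is the mean held-out squared error instead.
#' @return list with `table`, `r` and `flag` (reason when `r` is NA).
#' @export
bnLtrAgreement <- function(pairs, fits, threshold = 20L,
                           statistic = c("pearson", "mse")) {
  statistic <- match.arg(statistic)
  keyed <- .pairKey(pairs$from, pairs$to)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fit <- fits[[keyed[[i]]]]
    if (is.null(fit) || pairs$count[[i]] < threshold) return(NULL)
    if (isDegenerate(fit)) return(NULL)
    y <- if (statistic == "pearson") meanPearson(fit) else
      mean(vapply(fit@folds, function(f) {
        if (all(f$alpha == 0)) NA_real_ else f$mse
      }, numeric(1)), na.rm = TRUE)
    data.frame(from = pairs$from[[i]], to = pairs$to[[i]],
               count = pairs$count[[i]], logCount = log(pairs$count[[i]]),
               ltr = y)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(from = character(0), to = character(0),
                                      count = numeric(0),
                                      logCount = numeric(0), ltr = numeric(0))
  flag <- NA_character_
  r <- NA_real_
  if (nrow(tab) < 3L) flag <- "fewer than 3 retained pairs"
  else if (sd(tab$logCount) == 0 || sd(tab$ltr) == 0)
    flag <- "zero variance on an axis"
  else r <- cor(tab$logCount, tab$ltr)
  list(table = tab, r = r, flag = flag)
}
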