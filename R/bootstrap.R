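# Bootstrap edge confidence, differential edges between conditions,
# cross-dataset enhancement, and the permutation significance test.

# Fraction table straight from per-cell label vectors (avoids subsetting
# the expression matrix inside the bootstrap loop).
.labelFractions <- function(sample_id, cell_type, condition,
                            minCells = 100, samples = NULL,
                            keepTypes = NULL) {
  if (is.null(samples)) samples <- sort(unique(sample_id))
  empty <- setdiff(samples, sample_id)
  if (length(empty))
    stop("sample(s) with zero cells: ", paste(empty, collapse = ", "))
  sf <- factor(sample_id, levels = samples)
  tf <- factor(cell_type)
  counts <- unclass(table(sf, tf))
  totals <- rowSums(counts)
  keep <- if (is.null(keepTypes)) colSums(counts) >= minCells
          else colnames(counts) %in% keepTypes
  if (!any(keep)) stop("no cell type retained")
  frac <- sweep(counts[, keep, drop = FALSE], 1L, totals, "/")
  cond <- vapply(split(condition, sf), function(x) x[[1L]], character(1))
  new("FractionTable",
      values = matrix(frac, nrow = nrow(frac),
                      dimnames = list(samples, colnames(counts)[keep])),
      conditions = unname(cond))
}

#' Bootstrap edge counts for one condition
#'
#' Repeats the composition pipeline on random cell subsamples of one
#' condition and tallies how often each directed edge is returned by
#' structure learning. Per iteration, `floor(cellFrac * n)` of the
#' condition's cells are drawn without replacement, cell type fractions
#' are recomputed, re-discretized and a network is learned; the edge
#' tallies over `nIter` iterations are the edge confidence scores. The set
#' of retained cell types (the `minCells` filter) is fixed once on the full
#' condition data so every iteration scores the same node set. An
#' iteration in which some sample loses all its cells is redrawn once and
#' then raises an error.
#'
#' @param sce a `SingleCellExperiment` with `sample_id`, `condition` and
#'   `cell_type` columns in its `colData`.
#' @param condition which condition to analyse.
#' @param nIter number of bootstrap iterations (default 100).
#' @param cellFrac fraction of cells drawn per iteration, in (0, 1\]
#'   (default 0.8).
#' @param minCells abundance filter for retained cell types (default 100).
#' @param alpha,maxCondSize independence-test parameters of [hitonPC()].
#' @param strategy discretization strategy, see [discretizeFractions()].
#' @param seed integer seed; iteration seeds are derived from it and the
#'   whole run is reproducible.
#' @return an [EdgeCountTable-class].
#' @export
bootstrapEdges <- function(sce, condition, nIter = 100L, cellFrac = 0.8,
                           minCells = 100, alpha = 0.003, maxCondSize = 3L,
                           elimAlpha = alpha, strategy = "gmm",
                           seed = 1L) {
  stopifnot(cellFrac > 0, cellFrac <= 1, nIter >= 1)
  cd <- SummarizedExperiment::colData(sce)
  idx <- which(cd$condition == condition)
  if (!length(idx)) stop("no cells with condition '", condition, "'")
  sample_id <- as.character(cd$sample_id[idx])
  cell_type <- as.character(cd$cell_type[idx])
  condv <- as.character(cd$condition[idx])
  samples <- unique(sample_id)
  full <- table(factor(cell_type))
  keepTypes <- names(full)[full >= minCells]
  if (!length(keepTypes))
    stop("no cell type reaches minCells = ", minCells)
  types <- sort(keepTypes)
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(types, types))
  nDraw <- floor(cellFrac * length(idx))
  for (i in seq_len(nIter)) {
    old <- .safeSetSeed(.deriveSeed(seed, i))
    ft <- NULL
    for (attempt in 1:2) {
      sub <- sample.int(length(idx), nDraw)
      ft <- tryCatch(
        .labelFractions(sample_id[sub], cell_type[sub], condv[sub],
                        samples = samples, keepTypes = keepTypes),
        error = function(e) NULL)
      if (!is.null(ft)) break
    }
    .restoreSeed(old)
    if (is.null(ft))
      stop("bootstrap iteration ", i,
           " lost all cells of a sample twice; increase cellFrac")
    # the mixture-fit seed is shared across iterations: only the cell
    # subsample varies, so a run with cellFrac = 1 is fully deterministic
    bm <- discretizeFractions(ft, strategy, seed = seed)
    dag <- learnNetwork(bm, alpha = alpha, maxCondSize = maxCondSize,
                        elimAlpha = elimAlpha)
    e <- dag@edges
    for (r in seq_len(nrow(e)))
      counts[e[r, 1L], e[r, 2L]] <- counts[e[r, 1L], e[r, 2L]] + 1L
  }
  new("EdgeCountTable", counts = counts, nIter = as.integer(nIter),
      condition = condition)
}

#' Differential edges between case and control
#'
#' Unions the directed pairs whose bootstrap count reaches `threshold` in
#' either condition and scores each as case count minus control count. A
#' positive score means the interaction was found more often in the case
#' condition; negative, more often in control.
#'
#' @param case,control [EdgeCountTable-class] objects with the same
#'   `nIter` and cell type vocabulary.
#' @param threshold minimum bootstrap count in at least one condition
#'   (default 20).
#' @return data.frame with columns `from`, `to`, `case_count`,
#'   `control_count`, `score`, sorted by `|score|` descending, ties
#'   lexicographic.
#' @export
differentialEdges <- function(case, control, threshold = 20L) {
  if (case@nIter != control@nIter)
    stop("case and control tables have different nIter")
  if (!identical(sort(rownames(case@counts)), sort(rownames(control@counts))))
    stop("case and control tables cover different cell types")
  types <- rownames(case@counts)
  cc <- case@counts
  kk <- control@counts[types, types]
  sel <- which(pmax(cc, kk) >= threshold & !diag(length(types)),
               arr.ind = TRUE)
  df <- data.frame(from = types[sel[, 1L]], to = types[sel[, 2L]],
                   case_count = cc[sel], control_count = kk[sel])
  df$score <- df$case_count - df$control_count
  df <- df[order(-abs(df$score), df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Enhancement of differential edges by an added dataset
#'
#' Compares the differential edges of an original analysis with those of a
#' combined analysis (original plus an independent dataset). A pair is
#' "enhanced" when its signed score keeps its sign and grows in magnitude
#' after the new data are added.
#'
#' @param original,combined each a list with elements `case` and `control`
#'   holding [EdgeCountTable-class] objects.
#' @param threshold differential threshold applied to the original
#'   analysis (default 20).
#' @return data.frame with columns `from`, `to`, `original_score`,
#'   `combined_score`, `enhanced`.
#' @export
enhancementAnalysis <- function(original, combined, threshold = 20L) {
  dOrig <- differentialEdges(original$case, original$control, threshold)
  typesO <- rownames(original$case@counts)
  typesC <- rownames(combined$case@counts)
  unmapped <- setdiff(typesO, typesC)
  if (length(unmapped))
    stop("cell type(s) absent from the combined vocabulary: ",
         paste(unmapped, collapse = ", "))
  cs <- combined$case@counts - combined$control@counts[typesC, typesC]
  comb <- cs[cbind(match(dOrig$from, typesC), match(dOrig$to, typesC))]
  data.frame(from = dOrig$from, to = dOrig$to,
             original_score = dOrig$score, combined_score = comb,
             enhanced = sign(comb) == sign(dOrig$score) &
               abs(comb) > abs(dOrig$score))
}

#' Permutation test for cross-dataset agreement
#'
#' Asks whether an independent dataset enhances the original differential
#' edges more than chance. The observed statistic is the fraction of the
#' original differential pairs that are enhanced (see
#' [enhancementAnalysis()]) when the new dataset is added. The null is
#' built by repeatedly shuffling the new dataset's composition — by
#' default each sample's cell-type labels are permuted across types
#' (destroying type-type covariation while keeping each sample's value
#' multiset fixed) — and recomputing the enhanced fraction. The p-value
#' uses the add-one estimator `(1 + #(null >= observed)) / (1 + nPerm)`,
#' so it is never exactly zero.
#'
#' @param sceBase,sceNew the original and the added dataset; both need the
#'   same two condition labels and a shared cell type vocabulary.
#' @param nPerm number of permutations (default 100; below 20 a warning is
#'   emitted because the p-value resolution is coarser than 0.05).
#' @param threshold differential threshold (default 20).
#' @param nIter bootstrap iterations per network (default 20; the
#'   permutation loop multiplies this cost).
#' @param axis `"types"` (default) shuffles each sample's labels across
#'   cell types; `"samples"` reassigns each cell type's per-sample blocks
#'   across samples.
#' @param minCells,cellFrac,seed as in [bootstrapEdges()].
#' @return list with `p`, `observed`, `null` (numeric vector of length
#'   `nPerm`) and the observed enhancement table.
#' @export
permutationTest <- function(sceBase, sceNew, nPerm = 100L, threshold = 20L,
                            nIter = 20L, axis = c("types", "samples"),
                            minCells = 100, cellFrac = 0.8, seed = 1L) {
  axis <- match.arg(axis)
  if (nPerm < 20L)
    warning("nPerm < 20: p-value resolution is coarser than 0.05")
  base <- .cellLabels(sceBase)
  newd <- .cellLabels(sceNew)
  conds <- sort(unique(base$condition))
  if (length(conds) != 2L)
    stop("base dataset must have exactly two conditions")
  orig <- .labelBootstrapPair(base, conds, nIter, cellFrac, minCells,
                              seed = .deriveSeed(seed, 1e6))
  enhFrac <- function(labNew, s) {
    comb <- rbind(base, labNew)
    tabs <- .labelBootstrapPair(comb, conds, nIter, cellFrac, minCells,
                                seed = s)
    enh <- enhancementAnalysis(orig, tabs, threshold)
    if (!nrow(enh)) return(list(frac = 0, table = enh))
    list(frac = mean(enh$enhanced), table = enh)
  }
  obs <- enhFrac(newd, .deriveSeed(seed, 2e6))
  null <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    old <- .safeSetSeed(.deriveSeed(seed, p))
    perm <- .shuffleLabels(newd, axis)
    .restoreSeed(old)
    null[p] <- enhFrac(perm, .deriveSeed(seed, 3e6 + p))$frac
  }
  pval <- (1 + sum(null >= obs$frac)) / (1 + nPerm)
  list(p = pval, observed = obs$frac, null = null, table = obs$table)
}

.cellLabels <- function(sce) {
  cd <- SummarizedExperiment::colData(sce)
  data.frame(sample_id = as.character(cd$sample_id),
             condition = as.character(cd$condition),
             cell_type = as.character(cd$cell_type))
}

# bootstrap both conditions from label data only (no expression needed)
.labelBootstrapPair <- function(labels, conds, nIter, cellFrac, minCells,
                                seed) {
  one <- function(cond, s) {
    sub <- labels[labels$condition == cond, ]
    .bootstrapLabels(sub, nIter, cellFrac, minCells, seed = s)
  }
  list(case = one(conds[[2L]], .deriveSeed(seed, 11L)),
       control = one(conds[[1L]], .deriveSeed(seed, 22L)))
}

.bootstrapLabels <- function(labels, nIter, cellFrac, minCells, seed,
                             alpha = 0.003, maxCondSize = 3L) {
  full <- table(factor(labels$cell_type))
  keepTypes <- names(full)[full >= minCells]
  if (!length(keepTypes)) stop("no cell type retained")
  types <- sort(keepTypes)
  samples <- unique(labels$sample_id)
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(types, types))
  nDraw <- floor(cellFrac * nrow(labels))
  for (i in seq_len(nIter)) {
    old <- .safeSetSeed(.deriveSeed(seed, i))
    ft <- NULL
    for (attempt in 1:2) {
      sub <- sample.int(nrow(labels), nDraw)
      ft <- tryCatch(
        .labelFractions(labels$sample_id[sub], labels$cell_type[sub],
                        labels$condition[sub], samples = samples,
                        keepTypes = keepTypes),
        error = function(e) NULL)
      if (!is.null(ft)) break
    }
    .restoreSeed(old)
    if (is.null(ft)) stop("bootstrap iteration ", i, " lost a sample twice")
    bm <- discretizeFractions(ft, "gmm", seed = seed)
    dag <- learnNetwork(bm, alpha = alpha, maxCondSize = maxCondSize)
    e <- dag@edges
    for (r in seq_len(nrow(e)))
      counts[e[r, 1L], e[r, 2L]] <- counts[e[r, 1L], e[r, 2L]] + 1L
  }
  new("EdgeCountTable", counts = counts, nIter = as.integer(nIter),
      condition = paste(unique(labels$condition), collapse = "+"))
}

# shuffle the composition structure of a label table
.shuffleLabels <- function(labels, axis) {
  out <- labels
  if (axis == "types") {
    for (s in unique(labels$sample_id)) {
      i <- labels$sample_id == s
      types <- unique(labels$cell_type[i])
      newt <- setNames(sample(types), types)
      out$cell_type[i] <- unname(newt[labels$cell_type[i]])
    }
  } else {
    samples <- unique(labels$sample_id)
    for (tp in unique(labels$cell_type)) {
      i <- labels$cell_type == tp
      remap <- setNames(sample(samples), samples)
      out$sample_id[i] <- unname(remap[labels$sample_id[i]])
    }
  }
  out
}

#' Undirected bootstrap tally
#'
#' Diagnostic view of an edge count table with the two directions of
#' each pair summed; useful because edge orientation inside an
#' equivalence class is a tie-break, not evidence.
#'
#' @param ect an [EdgeCountTable-class].
#' @return symmetric integer matrix of per-pair counts.
#' @export
undirectedCounts <- function(ect) {
  ct <- ect@counts
  ct + t(ct)
}

#' Serialize an edge count table or differential edge table
#'
#' @param x an [EdgeCountTable-class] or the data.frame returned by
#'   [differentialEdges()].
#' @param path output TSV path.
#' @param header optional provenance comment line.
#' @export
writeEdgeTable <- function(x, path, header = NULL) {
  if (is(x, "EdgeCountTable")) {
    idx <- which(x@counts > 0, arr.ind = TRUE)
    df <- data.frame(from = rownames(x@counts)[idx[, 1L]],
                     to = colnames(x@counts)[idx[, 2L]],
                     count = x@counts[idx])
    df <- df[order(-df$count, df$from, df$to), , drop = FALSE]
    .writeTsv(df, path, header = header)
  } else {
    .writeTsv(x, path, header = header)
  }
}
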