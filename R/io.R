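#' Load an annotated expression matrix
#'
#' Reads a cells-by-genes expression dataset plus its per-cell metadata into
#' a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' (genes as rows, cells as columns, metadata in `colData`). Two on-disk
#' layouts are supported: Matrix Market triplets (`.mtx`, genes x cells,
#' with a sidecar gene table) or a dense delimited table with cells as rows
#' and gene ids in the header.
#'
#' The cell metadata table must provide the columns `sample_id`,
#' `condition` and `cell_type`; a `barcode` column, when present, supplies
#' the cell names. An optional two-column rename map (`from`, `to`) is
#' applied to `cell_type` at load time, which is how cell type vocabularies
#' of independent datasets are merged before a combined analysis.
#'
#' @param matrixPath path to the `.mtx` file or dense CSV/TSV.
#' @param cellsPath path to the per-cell metadata table.
#' @param genesPath path to the gene id table (required for `.mtx`; for a
#'   dense table it overrides the header if given).
#' @param renameMap optional data.frame with columns `from`, `to`, or a path
#'   to such a table.
#' @return a `SingleCellExperiment` with assay `"counts"`.
#' @examples
#' truth <- makeTruth(nTypes = 4, nEdges = 2, seed = 1)
#' sce <- simulateDataset(truth, nSamples = 4, cellsPerSample = 50, seed = 1)
#' d <- tempfile(); writeExpression(sce, d)
#' sce2 <- loadExpression(file.path(d, "matrix.mtx"),
#'                        file.path(d, "cells.tsv"),
#'                        file.path(d, "genes.tsv"))
#' stopifnot(identical(dim(sce2), dim(sce)))
#' @export
loadExpression <- function(matrixPath, cellsPath, genesPath = NULL,
                           renameMap = NULL) {
  if (!file.exists(matrixPath))
    stop("input file not found: ", matrixPath)
  cells <- .readTable(cellsPath)
  need <- c("sample_id", "condition", "cell_type")
  missing <- setdiff(need, colnames(cells))
  if (length(missing))
    stop("cell metadata table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (grepl("\\.mtx$", matrixPath, ignore.case = TRUE)) {
    if (is.null(genesPath))
      stop("genesPath is required for Matrix Market input")
    # `* 1` promotes pattern/logical matrices (how writeMM encodes
    # binary data) to numeric
    mat <- as(Matrix::readMM(matrixPath) * 1, "CsparseMatrix")
    genes <- .readTable(genesPath, header = FALSE)[, 1L]
    if (nrow(mat) != length(genes))
      stop(sprintf(paste0("gene axis mismatch: matrix has %d rows but the ",
                          "gene table has %d entries"),
                   nrow(mat), length(genes)))
    if (ncol(mat) != nrow(cells))
      stop(sprintf(paste0("cell axis mismatch: matrix has %d columns but ",
                          "the cell table has %d rows"),
                   ncol(mat), nrow(cells)))
  } else {
    dense <- .readTable(matrixPath)
    genes <- colnames(dense)
    if (!is.null(genesPath))
      genes <- .readTable(genesPath, header = FALSE)[, 1L]
    mat <- t(as.matrix(dense))
    if (nrow(mat) != length(genes))
      stop(sprintf(paste0("gene axis mismatch: matrix has %d genes but the ",
                          "gene table has %d entries"),
                   nrow(mat), length(genes)))
    if (ncol(mat) != nrow(cells))
      stop(sprintf(paste0("cell axis mismatch: matrix has %d rows (cells) ",
                          "but the cell table has %d rows"),
                   nrow(dense), nrow(cells)))
    mat <- as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  }
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  if (any(mat@x < 0) || any(!is.finite(mat@x)))
    stop("expression values must be finite and non-negative")
  rownames(mat) <- genes
  colnames(mat) <- if ("barcode" %in% colnames(cells)) cells$barcode else
    sprintf("cell%d", seq_len(ncol(mat)))
  if (!is.null(renameMap)) {
    if (is.character(renameMap) && length(renameMap) == 1L)
      renameMap <- .readTable(renameMap)
    if (!all(c("from", "to") %in% colnames(renameMap)))
      stop("renameMap needs columns 'from' and 'to'")
    hit <- match(cells$cell_type, renameMap$from)
    cells$cell_type[!is.na(hit)] <- renameMap$to[hit[!is.na(hit)]]
  }
  cd <- S4Vectors::DataFrame(sample_id = as.character(cells$sample_id),
                             condition = as.character(cells$condition),
                             cell_type = as.character(cells$cell_type))
  extra <- setdiff(colnames(cells), c(need, "barcode"))
  for (col in extra) cd[[col]] <- cells[[col]]
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = mat), colData = cd)
}

#' Write an annotated expression dataset
#'
#' Serializes a `SingleCellExperiment` to the Matrix Market layout that
#' [loadExpression()] reads (`matrix.mtx`, `genes.tsv`, `cells.tsv`).
#'
#' @param sce the dataset.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeExpression <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  cd <- SummarizedExperiment::colData(sce)
  cells <- data.frame(barcode = colnames(sce),
                      as.data.frame(cd), check.names = FALSE)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a ligand-target regulatory potential matrix
#'
#' Reads a delimited numeric table with target genes as rows (first column
#' holds the target names) and ligands as columns.
#'
#' @param path path to a TSV/CSV table.
#' @return a [LigandTargetMatrix-class].
#' @export
loadLigandTargetMatrix <- function(path) {
  raw <- .readTable(path, check.names = FALSE)
  tg <- as.character(raw[[1L]])
  lig <- colnames(raw)[-1L]
  if (anyDuplicated(lig))
    stop("duplicated ligand column name(s): ",
         paste(unique(lig[duplicated(lig)]), collapse = ", "))
  if (anyDuplicated(tg))
    stop("duplicated target name(s): ",
         paste(unique(tg[duplicated(tg)]), collapse = ", "))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric value at row %d, column '%s'", bad, lig[j]))
    }
  }
  p <- as.matrix(vals)
  dimnames(p) <- list(tg, lig)
  newLigandTargetMatrix(p)
}

#' @rdname LigandTargetMatrix-class
#' @param potential numeric matrix (targets x ligands) with dimnames.
#' @export
newLigandTargetMatrix <- function(potential)
  new("LigandTargetMatrix", potential = potential)

#' Cell type fractions per sample
#'
#' Tabulates the per-sample composition of a dataset: the fraction of each
#' cell type among all annotated cells of the sample. Cell types with fewer
#' than `minCells` cells pooled over all samples are dropped from the
#' columns, but their cells still count in each sample's denominator, so
#' retained fractions are unchanged by the filter and per-sample sums over
#' retained types are at most 1.
#'
#' @param sce a `SingleCellExperiment` from [loadExpression()] or
#'   [simulateDataset()].
#' @param minCells minimum pooled cell count for a type to be retained
#'   (default 100).
#' @param samples optional character vector of sample ids that must all be
#'   present; a listed sample with zero cells raises an error.
#' @return a [FractionTable-class].
#' @examples
#' truth <- makeTruth(nTypes = 4, nEdges = 2, seed = 1)
#' sce <- simulateDataset(truth, nSamples = 4, cellsPerSample = 100, seed = 1)
#' ft <- computeFractions(sce, minCells = 10)
#' rowSums(fractions(ft))
#' @export
computeFractions <- function(sce, minCells = 100, samples = NULL) {
  cd <- SummarizedExperiment::colData(sce)
  ft <- tryCatch(
    .labelFractions(as.character(cd$sample_id), as.character(cd$cell_type),
                    as.character(cd$condition), minCells = minCells,
                    samples = samples),
    error = function(e) {
      if (grepl("no cell type retained", conditionMessage(e)))
        stop("no cell type reaches minCells = ", minCells, call. = FALSE)
      stop(e)
    })
  ft
}

#' @rdname FractionTable-class
#' @param values numeric samples x cell types matrix of fractions.
#' @param conditions per-sample condition labels.
#' @export
newFractionTable <- function(values, conditions)
  new("FractionTable", values = values, conditions = as.character(conditions))

#' Serialize binary abundance states
#'
#' @param bm a [BinaryMatrix-class].
#' @param path output TSV path.
#' @export
writeBinaryMatrix <- function(bm, path) {
  df <- data.frame(sample = rownames(bm@states),
                   condition = bm@conditions, bm@states,
                   check.names = FALSE)
  .writeTsv(df, path)
}

.readTable <- function(path, header = TRUE, check.names = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = header, check.names = check.names,
             stringsAsFactors = FALSE, comment.char = "#")
}
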