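#' @import methods
#' @importFrom stats dnorm kmeans p.adjust pchisq cor rnorm rpois runif
#'   rbinom sd var uniroot quantile median setNames predict rmultinom
#' @importFrom utils read.delim write.table head combn
NULL

#' Per-sample cell type composition
#'
#' Holds the fraction of each retained cell type in each sample, together
#' with the per-sample condition label. Rows are samples, columns cell
#' types; values lie in \[0, 1\] and per-sample sums over retained types are
#' at most 1 (types below the abundance filter are dropped from the columns
#' but still count in the denominator).
#'
#' @slot values numeric matrix (samples x cell types) of fractions.
#' @slot conditions character vector of per-sample condition labels,
#'   parallel to the rows of `values`.
#'
#' @seealso [computeFractions()], [discretizeFractions()]
#' @export
setClass("FractionTable",
  representation(values = "matrix", conditions = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (nrow(v) < 2L) msg <- c(msg, "need at least 2 samples")
    if (any(!is.finite(v))) msg <- c(msg, "fractions must be finite")
    if (is.numeric(v) && length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "fractions must lie in [0, 1]")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must carry sample and cell type dimnames")
    if (length(object@conditions) != nrow(v))
      msg <- c(msg, "one condition label per sample required")
    if (length(msg)) msg else TRUE
  })

#' Binary cell type abundance states
#'
#' The discretized counterpart of a [FractionTable-class]: 0 marks the
#' low-abundance regime of a cell type, 1 the high-abundance regime. One
#' column per cell type; the `strategy` slot records, per column, whether
#' the mixture model or the midpoint fallback produced the labels.
#'
#' @slot states integer matrix of 0/1 states (samples x cell types).
#' @slot conditions per-sample condition labels.
#' @slot strategy character per cell type, `"gmm"` or `"midpoint"`.
#' @export
setClass("BinaryMatrix",
  representation(states = "matrix", conditions = "character",
                 strategy = "character"),
  validity = function(object) {
    s <- object@states
    msg <- character()
    if (!all(s %in% c(0L, 1L))) msg <- c(msg, "states must be 0/1")
    if (length(object@conditions) != nrow(s))
      msg <- c(msg, "one condition label per sample required")
    if (length(object@strategy) != ncol(s))
      msg <- c(msg, "one strategy entry per cell type required")
    if (length(msg)) msg else TRUE
  })

#' Directed acyclic graph over cell types
#'
#' @slot nodes character vector of node (cell type) names.
#' @slot edges two-column character matrix of directed edges (from, to).
#' @export
setClass("Dag",
  representation(nodes = "character", edges = "matrix"),
  validity = function(object) {
    e <- object@edges
    msg <- character()
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else {
      if (!all(e %in% object@nodes))
        msg <- c(msg, "edge endpoints must be nodes")
      if (nrow(e) && any(e[, 1L] == e[, 2L]))
        msg <- c(msg, "self loops are not allowed")
      if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node names")
      if (nrow(e) && anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
        msg <- c(msg, "duplicate edges")
      if (!.isAcyclic(object@nodes, e))
        msg <- c(msg, "graph contains a directed cycle")
    }
    if (length(msg)) msg else TRUE
  })

#' Discrete Bayesian network: structure plus conditional probability tables
#'
#' @slot dag the [Dag-class] structure.
#' @slot cpts named list, one element per node: a numeric matrix with one
#'   row per parent configuration (binary order, first parent is the least
#'   significant bit) and columns `"0"`/`"1"`; rows sum to 1.
#' @export
setClass("BnModel",
  representation(dag = "Dag", cpts = "list"),
  validity = function(object) {
    msg <- character()
    nd <- object@dag@nodes
    if (!identical(sort(names(object@cpts)), sort(nd)))
      msg <- c(msg, "cpts must be named by the dag nodes")
    for (q in names(object@cpts)) {
      cpt <- object@cpts[[q]]
      np <- sum(object@dag@edges[, 2L] == q)
      if (nrow(cpt) != 2L^np)
        msg <- c(msg, sprintf("cpt of %s has %d rows, expected %d",
                              q, nrow(cpt), 2L^np))
      if (any(abs(rowSums(cpt) - 1) > 1e-9))
        msg <- c(msg, sprintf("cpt rows of %s must sum to 1", q))
    }
    if (length(msg)) msg else TRUE
  })

#' Bootstrap edge counts for one condition
#'
#' Number of bootstrap iterations in which each directed cell-type pair was
#' returned by structure learning, out of `nIter` cell-subsampled runs.
#'
#' @slot counts integer matrix (from x to), zero diagonal.
#' @slot nIter number of bootstrap iterations.
#' @slot condition the condition the table was computed for.
#' @export
setClass("EdgeCountTable",
  representation(counts = "matrix", nIter = "integer", condition = "character"),
  validity = function(object) {
    msg <- character()
    ct <- object@counts
    if (nrow(ct) != ncol(ct) ||
        !identical(rownames(ct), colnames(ct)))
      msg <- c(msg, "counts must be square with matching dimnames")
    if (any(ct < 0) || any(ct > object@nIter))
      msg <- c(msg, "counts must lie in [0, nIter]")
    if (nrow(ct) && any(diag(ct) != 0))
      msg <- c(msg, "self pairs must have zero count")
    if (length(msg)) msg else TRUE
  })

#' Ligand-target regulatory potential matrix
#'
#' Prior knowledge of how strongly each ligand is expected to regulate each
#' target gene (e.g. a NicheNet-derived potential matrix). Targets are
#' rows, ligands columns.
#'
#' @slot potential numeric matrix (targets x ligands) with dimnames.
#' @export
setClass("LigandTargetMatrix",
  representation(potential = "matrix"),
  validity = function(object) {
    p <- object@potential
    msg <- character()
    if (is.null(rownames(p)) || is.null(colnames(p)))
      msg <- c(msg, "potential must carry target and ligand names")
    else {
      if (anyDuplicated(rownames(p))) msg <- c(msg, "duplicate target names")
      if (anyDuplicated(colnames(p))) msg <- c(msg, "duplicate ligand names")
    }
    if (any(!is.finite(p))) msg <- c(msg, "potential must be finite")
    if (ncol(p) && any(colSums(abs(p)) == 0))
      msg <- c(msg, "every ligand column needs at least one nonzero entry")
    if (length(msg)) msg else TRUE
  })

#' Fitted ligand-target regression
#'
#' Cross-validated LASSO fit with one shared activity coefficient per
#' ligand. `folds` holds, per fold, the coefficient vector `alpha`, the
#' intercept, the selected penalty `lambda` and the held-out Pearson
#' correlation (NA for an all-zero fold). `degenerate` is TRUE when every
#' fold shrank all coefficients to zero; such fits are excluded from
#' correlation summaries.
#'
#' @slot folds list of per-fold fit records.
#' @slot meanPearson mean held-out Pearson correlation over non-degenerate
#'   folds (NA when degenerate).
#' @slot degenerate logical flag.
#' @export
setClass("LtrFit",
  representation(folds = "list", meanPearson = "numeric",
                 degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    for (f in object@folds) {
      if (!all(c("alpha", "lambda", "pearson") %in% names(f)))
        msg <- c(msg, "each fold needs alpha, lambda and pearson")
    }
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a composition simulation
#'
#' A generating Bayesian network over binary cell-type abundance states
#' plus the observation model turning states into samples of annotated
#' cells: per-type fraction distributions for the low/high state, marker
#' gene sets, Poisson expression rates and a Bernoulli dropout rate.
#'
#' @slot model [BnModel-class] over cell types (abundance states).
#' @slot fractionMap numeric matrix (types x 3: low, high, sd).
#' @slot markers named list, cell type to marker gene ids.
#' @slot geneIds all gene ids of the simulated panel.
#' @slot baselineExpr,markerExpr Poisson rates for background and marker
#'   genes.
#' @slot dropout probability that an observed count is zeroed, in \[0, 1).
#' @slot backgroundWeight per-population mean raw weights of stable
#'   background cell types (`BG01`, `BG02`, ...) that anchor the
#'   composition denominator; length 0 disables the anchor.
#' @slot backgroundSd spread of each background weight across samples.
#' @slot polarity per-type +1/-1: whether abundance state 1 maps to the
#'   high (+1) or the low (-1) fraction regime, i.e. whether the type is
#'   promoted or suppressed when its state switches on.
#' @export
setClass("SimulationTruth",
  representation(model = "BnModel", fractionMap = "matrix",
                 markers = "list", geneIds = "character",
                 baselineExpr = "numeric", markerExpr = "numeric",
                 dropout = "numeric", backgroundWeight = "numeric",
                 backgroundSd = "numeric", polarity = "numeric"),
  validity = function(object) {
    msg <- character()
    fm <- object@fractionMap
    if (!identical(colnames(fm), c("low", "high", "sd")))
      msg <- c(msg, "fractionMap needs columns low, high, sd")
    else if (any(fm[, "low"] >= fm[, "high"]))
      msg <- c(msg, "low state mean must be below high state mean")
    if (object@dropout < 0 || object@dropout >= 1)
      msg <- c(msg, "dropout must lie in [0, 1)")
    if (length(object@polarity) != length(object@model@dag@nodes) ||
        !all(object@polarity %in% c(-1, 1)))
      msg <- c(msg, "polarity must be +1/-1 per modeled cell type")
    expect <- c(object@model@dag@nodes,
                sprintf("BG%02d", seq_along(object@backgroundWeight)))
    if (!identical(sort(names(object@markers)), sort(expect)))
      msg <- c(msg,
               "markers must cover the model's cell types (plus BG types)")
    if (length(msg)) msg else TRUE
  })
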