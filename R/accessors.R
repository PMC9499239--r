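# Accessors and show methods for the core S4 classes.

#' @rdname FractionTable-class
#' @export
setMethod("fractions", "FractionTable", function(x) x@values)

#' @rdname BinaryMatrix-class
#' @export
setMethod("states", "BinaryMatrix", function(x) x@states)

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "FractionTable", function(x) colnames(x@values))
#' @rdname cellTypes
#' @export
setMethod("cellTypes", "BinaryMatrix", function(x) colnames(x@states))
#' @rdname cellTypes
#' @export
setMethod("cellTypes", "EdgeCountTable", function(x) rownames(x@counts))
#' @rdname cellTypes
#' @export
setMethod("cellTypes", "Dag", function(x) x@nodes)
#' @rdname cellTypes
#' @export
setMethod("cellTypes", "SimulationTruth", function(x) x@model@dag@nodes)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "FractionTable", function(x) rownames(x@values))
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "BinaryMatrix", function(x) rownames(x@states))

#' @rdname sampleConditions
#' @export
setMethod("sampleConditions", "FractionTable", function(x) x@conditions)
#' @rdname sampleConditions
#' @export
setMethod("sampleConditions", "BinaryMatrix", function(x) x@conditions)

#' @rdname edges
#' @export
setMethod("edges", "Dag", function(x) x@edges)
#' @rdname edges
#' @export
setMethod("edges", "BnModel", function(x) x@dag@edges)
#' @rdname edges
#' @export
setMethod("edges", "SimulationTruth", function(x) x@model@dag@edges)

#' @rdname nodes
#' @export
setMethod("nodes", "Dag", function(x) x@nodes)
#' @rdname nodes
#' @export
setMethod("nodes", "BnModel", function(x) x@dag@nodes)

#' @rdname EdgeCountTable-class
#' @export
setMethod("edgeCounts", "EdgeCountTable", function(x) x@counts)

#' @rdname EdgeCountTable-class
#' @export
setMethod("nIter", "EdgeCountTable", function(x) x@nIter)

#' @rdname LigandTargetMatrix-class
#' @export
setMethod("potentials", "LigandTargetMatrix", function(x) x@potential)
#' @rdname LigandTargetMatrix-class
#' @export
setMethod("ligands", "LigandTargetMatrix", function(x) colnames(x@potential))
#' @rdname LigandTargetMatrix-class
#' @export
setMethod("targets", "LigandTargetMatrix", function(x) rownames(x@potential))

#' @rdname LtrFit-class
#' @export
setMethod("meanPearson", "LtrFit", function(x) x@meanPearson)
#' @rdname LtrFit-class
#' @export
setMethod("isDegenerate", "LtrFit", function(x) x@degenerate)

setMethod("show", "FractionTable", function(object) {
  cat(sprintf("FractionTable: %d samples x %d cell types\n",
              nrow(object@values), ncol(object@values)))
  cat("conditions:",
      paste(sprintf("%s (%d)", names(table(object@conditions)),
                    table(object@conditions)), collapse = ", "), "\n")
})

setMethod("show", "BinaryMatrix", function(object) {
  cat(sprintf("BinaryMatrix: %d samples x %d cell types\n",
              nrow(object@states), ncol(object@states)))
  nfall <- sum(object@strategy == "midpoint")
  if (nfall) cat(sprintf("  %d column(s) used the midpoint fallback\n", nfall))
})

setMethod("show", "Dag", function(object) {
  cat(sprintf("Dag: %d nodes, %d directed edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges)) {
    shown <- head(seq_len(nrow(object@edges)), 10L)
    cat(paste0("  ", object@edges[shown, 1L], " -> ",
               object@edges[shown, 2L], collapse = "\n"), "\n")
    if (nrow(object@edges) > 10L) cat("  ...\n")
  }
})

setMethod("show", "BnModel", function(object) {
  cat("BnModel\n")
  show(object@dag)
})

setMethod("show", "EdgeCountTable", function(object) {
  cat(sprintf("EdgeCountTable (%s): %d cell types, nIter = %d\n",
              object@condition, nrow(object@counts), object@nIter))
  cat(sprintf("  %d directed pairs with nonzero count\n",
              sum(object@counts > 0)))
})

setMethod("show", "LigandTargetMatrix", function(object) {
  cat(sprintf("LigandTargetMatrix: %d targets x %d ligands\n",
              nrow(object@potential), ncol(object@potential)))
})

setMethod("show", "LtrFit", function(object) {
  cat(sprintf("LtrFit: %d folds, %s\n", length(object@folds),
              if (object@degenerate) "degenerate (all-zero coefficients)"
              else sprintf("mean held-out Pearson = %.3f",
                           object@meanPearson)))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "SimulationTruth: %d cell types, %d ground-truth edges, dropout = %g\n",
    length(object@model@dag@nodes), nrow(object@model@dag@edges),
    object@dropout))
})
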