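#' @rdname FractionTable-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname BinaryMatrix-class
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Cell types covered by an object
#' @param x a FractionTable, BinaryMatrix, EdgeCountTable, Dag or
#'   SimulationTruth.
#' @return character vector of cell type names.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Sample identifiers of an object
#' @param x a FractionTable or BinaryMatrix.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Per-sample condition labels
#' @param x a FractionTable or BinaryMatrix.
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' Directed edges of a graph-bearing object
#' @param x a Dag, BnModel, EdgeCountTable or SimulationTruth.
#' @return two-column character matrix (from, to).
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Nodes of a graph-bearing object
#' @param x a Dag or BnModel.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname EdgeCountTable-class
#' @export
setGeneric("edgeCounts", function(x) standardGeneric("edgeCounts"))

#' @rdname EdgeCountTable-class
#' @export
setGeneric("nIter", function(x) standardGeneric("nIter"))

#' @rdname LigandTargetMatrix-class
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))

#' @rdname LigandTargetMatrix-class
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

#' @rdname LigandTargetMatrix-class
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname LtrFit-class
#' @export
setGeneric("meanPearson", function(x) standardGeneric("meanPearson"))

#' @rdname LtrFit-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
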