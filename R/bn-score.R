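# Scoring of discrete Bayesian networks over binary abundance states.
#
# The network score is the BIC: maximized log-likelihood minus
# 0.5 * Dim(G) * log(N), with Dim(G) = sum over nodes of 2^{#parents}
# (one free parameter per parent configuration of a binary node). The
# score decomposes over node families, which hill climbing exploits.

#' Construct a directed acyclic graph
#'
#' @param nodes character vector of node names.
#' @param edgeList two-column matrix or data.frame of directed edges
#'   (from, to); may have zero rows.
#' @return a [Dag-class]; construction fails if the edges form a cycle.
#' @examples
#' newDag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
newDag <- function(nodes, edgeList = NULL) {
  if (is.null(edgeList) || NROW(edgeList) == 0L)
    edgeList <- matrix(character(0), 0L, 2L)
  e <- as.matrix(edgeList)
  storage.mode(e) <- "character"
  colnames(e) <- c("from", "to")
  new("Dag", nodes = as.character(nodes), edges = e)
}

# samples x nodes integer matrix out of a BinaryMatrix or plain matrix
.stateMatrix <- function(data) {
  m <- if (is(data, "BinaryMatrix")) data@states else as.matrix(data)
  storage.mode(m) <- "integer"
  m
}

# parent index list per node for a Dag, in the column order of `nodes`
.parentList <- function(dag, nodes) {
  pl <- rep(list(integer(0)), length(nodes))
  names(pl) <- nodes
  e <- dag@edges
  for (i in seq_len(nrow(e)))
    pl[[e[i, 2L]]] <- c(pl[[e[i, 2L]]], match(e[i, 1L], nodes))
  pl
}

# counts of (state, parent config) for one family: 2 x 2^k matrix
.familyCounts <- function(D, q, pa) {
  k <- length(pa)
  cfg <- if (k) as.integer(D[, pa, drop = FALSE] %*% 2^(seq_len(k) - 1L))
         else integer(nrow(D))
  cnt <- tabulate(cfg * 2L + D[, q] + 1L, nbins = 2L^(k + 1L))
  matrix(cnt, nrow = 2L)
}

# maximized log-likelihood contribution of one family (0 log 0 = 0)
.familyLL <- function(D, q, pa) {
  cnt <- .familyCounts(D, q, pa)
  tot <- rep(colSums(cnt), each = 2L)
  nz <- cnt > 0
  sum(cnt[nz] * log(cnt[nz] / tot[nz]))
}

.familyBic <- function(D, q, pa, logN)
  .familyLL(D, q, pa) - 0.5 * 2^length(pa) * logN

#' Maximized log-likelihood of a network structure
#'
#' Log-probability of the binary data under the DAG with conditional
#' probability tables at their maximum-likelihood (relative frequency)
#' values; decomposes into one term per node family.
#'
#' @param data a [BinaryMatrix-class] or a plain 0/1 matrix whose columns
#'   cover the DAG's nodes.
#' @param dag a [Dag-class].
#' @return scalar log-likelihood (non-positive).
#' @export
bnLoglik <- function(data, dag) {
  D <- .stateMatrix(data)
  missing <- setdiff(dag@nodes, colnames(D))
  if (length(missing))
    stop("node(s) missing from data: ", paste(missing, collapse = ", "))
  if (!nrow(D)) stop("need at least one sample")
  pl <- .parentList(dag, colnames(D))
  sum(vapply(dag@nodes,
             function(q) .familyLL(D, match(q, colnames(D)), pl[[q]]),
             numeric(1)))
}

#' BIC score of a network structure
#'
#' `bnLoglik(data, dag) - 0.5 * Dim(G) * log(N)` with
#' `Dim(G) = sum_q 2^{|Pa(q)|}`; the objective maximized by [hillClimb()].
#'
#' @inheritParams bnLoglik
#' @return scalar BIC (larger is better).
#' @export
bicScore <- function(data, dag) {
  D <- .stateMatrix(data)
  dimG <- sum(vapply(dag@nodes,
                     function(q) 2^sum(dag@edges[, 2L] == q), numeric(1)))
  bnLoglik(data, dag) - 0.5 * dimG * log(nrow(D))
}

#' Estimate conditional probability tables for a fixed structure
#'
#' Relative-frequency CPT estimates with an optional symmetric pseudocount
#' (Laplace smoothing), one row per parent configuration. The default
#' pseudocount of 1 keeps unseen configurations at probability 1/2, which
#' the simulator relies on; use 0 for pure maximum likelihood.
#'
#' @inheritParams bnLoglik
#' @param pseudocount non-negative smoothing constant (default 1).
#' @return a [BnModel-class].
#' @export
fitCPTs <- function(data, dag, pseudocount = 1) {
  D <- .stateMatrix(data)
  stopifnot(pseudocount >= 0)
  pl <- .parentList(dag, colnames(D))
  cpts <- lapply(dag@nodes, function(q) {
    cnt <- .familyCounts(D, match(q, colnames(D)), pl[[q]])
    p1 <- (cnt[2L, ] + pseudocount) /
      (colSums(cnt) + 2 * pseudocount)
    k <- length(pl[[q]])
    m <- cbind("0" = 1 - p1, "1" = p1)
    rownames(m) <- if (k) apply(
      expand.grid(rep(list(0:1), k))[, seq_len(k), drop = FALSE], 1L,
      paste, collapse = "") else "."
    m
  })
  names(cpts) <- dag@nodes
  new("BnModel", dag = dag, cpts = cpts)
}

#' Export a DAG as an edge-list TSV or Graphviz DOT file
#'
#' @param dag a [Dag-class].
#' @param path output file.
#' @param format `"tsv"` (two columns, from/to) or `"dot"`.
#' @param header optional provenance comment for the TSV form.
#' @export
writeDag <- function(dag, path, format = c("tsv", "dot"), header = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    .writeTsv(as.data.frame(dag@edges), path, header = header)
  } else {
    lines <- c("digraph celltypes {",
               sprintf("  \"%s\";", dag@nodes),
               sprintf("  \"%s\" -> \"%s\";",
                       dag@edges[, 1L], dag@edges[, 2L]),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
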