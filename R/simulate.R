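# Synthetic case-control scRNA-seq generator. Per-sample binary abundance
# states are drawn from a known ground-truth Bayesian network; states map
# to composition fractions; cells are drawn multinomially and given
# Poisson marker/background expression with optional Bernoulli dropout.
# The per-cell `cell_type` annotation is re-derived from the observed
# (post-dropout) expression by a nearest-marker-score classifier, which is
# how expression noise propagates into the composition pipeline; the
# generating type is kept in `true_type`.

#' Construct a simulation ground truth
#'
#' Builds the generating network over `nTypes` cell types together with
#' its observation model. Two topologies are available:
#'
#' * `"cascade"` (default, the fixed study network): with the default 10
#'   types and 6 edges, two three-type cascades (`CT01 -> CT02 -> CT03`,
#'   `CT04 -> CT05 -> CT06`) plus two isolated interactions
#'   (`CT07 -> CT08`, `CT09 -> CT10`). A fixed network makes replicate
#'   runs comparable (only the data vary), and its maximum degree of 2
#'   keeps the number of adjacent edge pairs minimal: in a hub of
#'   near-copy children the sampled data can genuinely prefer a
#'   sibling-sibling edge over a true hub edge at a few dozen samples,
#'   a structure misidentification no learner can avoid.
#' * `"random"`: a random DAG with exactly `nEdges` edges (acyclic by
#'   construction via a random topological order). While `nEdges` allows
#'   it (`nEdges <= nTypes - 1`) the draw is constrained to in-degree at
#'   most 1 (a forest), so every planted edge is a direct noisy copy of a
#'   single parent: with several parents behind an OR/AND gate, a single
#'   parent's marginal association with the child is diluted to the
#'   chance level at realistic sample counts, i.e. the planted
#'   interaction would be undetectable in principle rather than merely
#'   hard.
#'
#' CPTs are strong-dependence: each child copies a noisy OR (or AND,
#' chosen per node) of its parents with flip probability `flipProb`;
#' roots are Bernoulli(0.5). Interaction strengths are heterogeneous, as
#' in real tissue: under the cascade topology the last planted edge uses
#' `weakEdgeFlip` instead of `flipProb`, placing one interaction near
#' the detection boundary of composition data at a few dozen samples.
#' The observation model maps state 0/1 to Gaussian fraction draws
#' around `fractionLow`/`fractionHigh` and gives each type
#' `markersPerType` private marker genes.
#'
#' @param nTypes number of cell types (default 10).
#' @param nEdges number of ground-truth edges (default 6); at most
#'   `nTypes * (nTypes - 1) / 2`.
#' @param seed integer seed.
#' @param flipProb CPT noise: probability the child deviates from its
#'   parents' OR/AND (default 0.1).
#' @param weakEdgeFlip flip probability of the weakest planted
#'   interaction (cascade topology only; default 0.35). Set equal to
#'   `flipProb` for homogeneous strengths.
#' @param subtleEdgeFlip flip probability of the moderate interaction
#'   between the transcriptionally subtle types (cascade topology only;
#'   default 0.17). Together with `subtleMarkerExpr` this yields a
#'   graded difficulty ladder: strong cascade interactions, one moderate
#'   interaction whose types are hard to annotate at reduced depth, and
#'   one weak interaction at the detection boundary.
#' @param fractionLow,fractionHigh,fractionSd state-conditional fraction
#'   means and their spread before renormalization (defaults 0.03, 0.12,
#'   0.005: the low/high regimes of a type differ fourfold while
#'   sample-to-sample variation within a regime stays well below the
#'   regime gap).
#' @param nGenes size of the simulated gene panel (default 200).
#' @param markersPerType private marker genes per type (default 5).
#' @param markerExpr,baselineExpr Poisson rates of marker and background
#'   counts (defaults 2.5 and 0.15; chosen so that ordinary types are
#'   annotated nearly perfectly even at 50% dropout, leaving the
#'   dropout response to the transcriptionally subtle types).
#'   `markerExpr` may be a vector over the modeled types.
#' @param subtleMarkerExpr marker rate of transcriptionally subtle types
#'   (default 0.58). Marker strength varies between real cell types, and
#'   subtle types are the first casualties of dropout: their cells are
#'   annotated nearly perfectly at full depth but are scrambled once
#'   half the counts are zeroed. Under the cascade topology the types of
#'   the first isolated interaction (`CT07`, `CT08` at the defaults)
#'   are the subtle ones; set equal to `markerExpr` to disable.
#' @param dropout Bernoulli zeroing probability in \[0, 1) (default 0).
#' @param polarity per-type +1/-1 vector, or `"alternating"` (default):
#'   whether a type is promoted (+1, state 1 maps to the high fraction
#'   regime) or suppressed (-1, state 1 maps to the low regime) when its
#'   abundance state switches on. Interactions in real tissue both
#'   promote and suppress their partners, and the default alternates
#'   polarity along each cascade. This also matters statistically:
#'   fractions share a renormalizing denominator, and if all correlated
#'   types moved in the same direction their aggregate state would leak
#'   into every other type's fraction through the denominator; with
#'   mixed signs the correlated contributions largely cancel.
#' @param nBackground,backgroundWeight,backgroundSd stable background
#'   populations (`BG01`, ..., cell types outside the truth network) added
#'   to every sample: `nBackground` types (default 3), each with raw
#'   weight drawn per sample from `N(backgroundWeight / nBackground,
#'   backgroundSd)` (defaults 1 total, sd 0.1). Compositions are closed
#'   (fractions sum to 1), so without an anchor the aggregate abundance
#'   state of the modeled types is absorbed into the shared denominator
#'   and leaks into every fraction; dominant stable populations — as real
#'   tissues have — keep the denominator nearly constant. The anchor is
#'   split over several types with independent weights so that no single
#'   column mirrors the residual common mode. `nBackground = 0` disables
#'   the anchor.
#' @param topology `"cascade"` (fixed study network, default) or
#'   `"random"` (seed-dependent random forest/DAG).
#' @return a [SimulationTruth-class].
#' @examples
#' truth <- makeTruth(seed = 1)
#' edges(truth)
#' @export
makeTruth <- function(nTypes = 10L, nEdges = 6L, seed = 1L,
                      topology = c("cascade", "random"),
                      flipProb = 0.1, weakEdgeFlip = 0.35,
                      subtleEdgeFlip = 0.17,
                      polarity = "alternating",
                      fractionLow = 0.03,
                      fractionHigh = 0.12, fractionSd = 0.005,
                      nGenes = 200L, markersPerType = 5L,
                      markerExpr = 2.5, subtleMarkerExpr = 0.58,
                      baselineExpr = 0.15,
                      dropout = 0, nBackground = 3L, backgroundWeight = 1,
                      backgroundSd = 0.1) {
  topology <- match.arg(topology)
  maxE <- nTypes * (nTypes - 1) / 2
  if (nEdges > maxE)
    stop("nEdges = ", nEdges, " exceeds the acyclic maximum of ", maxE)
  nMarked <- nTypes + nBackground
  if (nGenes < nMarked * markersPerType)
    stop("nGenes too small for ", nMarked, " x ", markersPerType,
         " markers")
  types <- sprintf("CT%02d", seq_len(nTypes))
  old <- .safeSetSeed(seed)
  on.exit(.restoreSeed(old))
  if (topology == "cascade") {
    # fixed chains over consecutive types, using as many isolated edges
    # as the type budget allows (each two-edge cascade spends 3 types,
    # each isolated edge 2); 10 types / 6 edges gives
    # CT01->CT02->CT03, CT04->CT05->CT06, CT07->CT08, CT09->CT10
    k2 <- max(0L, 2L * nEdges - nTypes)      # number of two-edge cascades
    k1 <- nEdges - 2L * k2                   # number of isolated edges
    if (k1 < 0L || 3L * k2 + 2L * k1 > nTypes)
      stop("cascade topology cannot place ", nEdges, " edges over ",
           nTypes, " types; use topology = 'random'")
    edgeList <- matrix(character(0), 0L, 2L)
    i <- 1L
    for (comp in c(rep(2L, k2), rep(1L, k1))) {
      for (k in seq_len(comp))
        edgeList <- rbind(edgeList, c(types[i + k - 1L], types[i + k]))
      i <- i + comp + 1L
    }
  } else if (nEdges <= nTypes - 1L) {
    # forest: each child has exactly one parent earlier in the order
    ord <- sample(types)                     # topological order
    children <- sample(2:nTypes, nEdges)
    parents <- vapply(children, function(j) sample.int(j - 1L, 1L),
                      integer(1))
    edgeList <- cbind(ord[parents], ord[children])
  } else {
    ord <- sample(types)
    pairs <- t(combn(nTypes, 2L))            # i < j in `ord`
    pick <- pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
    edgeList <- cbind(ord[pick[, 1L]], ord[pick[, 2L]])
  }
  dag <- newDag(types, edgeList)
  gateOr <- setNames(sample(c(TRUE, FALSE), nTypes, replace = TRUE), types)
  nodeFlip <- setNames(rep(flipProb, nTypes), types)
  if (topology == "cascade" && nrow(edgeList)) {
    nodeFlip[[edgeList[nrow(edgeList), 2L]]] <- weakEdgeFlip
    k2c <- max(0L, 2L * nEdges - nTypes)
    k1c <- nEdges - 2L * k2c
    if (k1c >= 2L)
      nodeFlip[[edgeList[2L * k2c + 1L, 2L]]] <- subtleEdgeFlip
  }
  cpts <- lapply(types, function(q) {
    pa <- edgeList[edgeList[, 2L] == q, 1L]
    k <- length(pa)
    if (k == 0L)
      return(matrix(c(0.5, 0.5), 1L, 2L, dimnames = list(".", c("0", "1"))))
    cfg <- as.matrix(expand.grid(rep(list(0:1), k)))
    base <- if (gateOr[[q]]) as.integer(rowSums(cfg) > 0)
            else as.integer(rowSums(cfg) == k)
    p1 <- ifelse(base == 1L, 1 - nodeFlip[[q]], nodeFlip[[q]])
    m <- cbind("0" = 1 - p1, "1" = p1)
    rownames(m) <- apply(cfg, 1L, paste, collapse = "")
    m
  })
  names(cpts) <- types
  model <- new("BnModel", dag = dag, cpts = cpts)
  fm <- matrix(rep(c(fractionLow, fractionHigh, fractionSd), each = nTypes),
               nTypes, 3L, dimnames = list(types, c("low", "high", "sd")))
  if (identical(polarity, "alternating")) {
    # alternate promoted/suppressed along each connected component
    nbr <- setNames(rep(list(character(0)), nTypes), types)
    for (i in seq_len(nrow(edgeList))) {
      a <- edgeList[i, 1L]; b <- edgeList[i, 2L]
      nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
    }
    pol <- setNames(rep(NA_real_, nTypes), types)
    for (start in types) {
      if (!is.na(pol[[start]])) next
      pol[[start]] <- 1
      queue <- start
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        for (w in nbr[[v]]) if (is.na(pol[[w]])) {
          pol[[w]] <- -pol[[v]]
          queue <- c(queue, w)
        }
      }
    }
    polarity <- unname(pol[types])
  } else {
    stopifnot(length(polarity) == nTypes, all(polarity %in% c(-1, 1)))
  }
  genes <- sprintf("G%03d", seq_len(nGenes))
  markers <- lapply(seq_len(nMarked), function(k)
    genes[((k - 1L) * markersPerType + 1L):(k * markersPerType)])
  names(markers) <- c(types, sprintf("BG%02d", seq_len(nBackground)))
  me <- rep_len(markerExpr, nTypes)
  if (topology == "cascade") {
    k2 <- max(0L, 2L * nEdges - nTypes)
    k1 <- nEdges - 2L * k2
    if (k1 >= 2L) {
      # the first isolated interaction involves the subtle types
      subtle <- as.character(edgeList[2L * k2 + 1L, ])
      me[match(subtle, types)] <- subtleMarkerExpr
    }
  }
  markerExprVec <- setNames(c(me, rep(max(me), nBackground)),
                            names(markers))
  new("SimulationTruth", model = model, fractionMap = fm,
      markers = markers, geneIds = genes, baselineExpr = baselineExpr,
      markerExpr = markerExprVec, dropout = dropout,
      backgroundWeight = rep(backgroundWeight / max(nBackground, 1L),
                             nBackground),
      backgroundSd = backgroundSd, polarity = polarity)
}

#' Ancestral sampling of abundance states from a network
#'
#' @param model a [BnModel-class].
#' @param nSamples number of joint draws.
#' @param seed integer seed.
#' @return integer 0/1 matrix, samples x nodes.
#' @export
sampleStates <- function(model, nSamples, seed = 1L) {
  dag <- model@dag
  nodes <- dag@nodes
  old <- .safeSetSeed(seed)
  on.exit(.restoreSeed(old))
  topo <- .topoOrder(nodes, dag@edges)
  out <- matrix(0L, nSamples, length(nodes),
                dimnames = list(NULL, nodes))
  for (q in topo) {
    pa <- dag@edges[dag@edges[, 2L] == q, 1L]
    if (!length(pa)) {
      p1 <- rep(model@cpts[[q]][1L, "1"], nSamples)
    } else {
      cfg <- 1L + as.integer(out[, pa, drop = FALSE] %*%
                               2L^(seq_along(pa) - 1L))
      p1 <- model@cpts[[q]][cfg, "1"]
    }
    out[, q] <- as.integer(runif(nSamples) < p1)
  }
  out
}

.topoOrder <- function(nodes, edges) {
  left <- nodes
  done <- character(0)
  while (length(left)) {
    ready <- left[vapply(left, function(q) {
      pa <- edges[edges[, 2L] == q, 1L]
      all(pa %in% done)
    }, logical(1))]
    done <- c(done, ready)
    left <- setdiff(left, ready)
  }
  done
}

#' Simulate an annotated case-control composition dataset
#'
#' Per sample: draw the joint abundance state from the truth network, map
#' states to fractions (Gaussian around the state-conditional mean,
#' truncated at 0.001, renormalized to sum to 1), draw cell counts
#' multinomially, and give each cell Poisson expression (marker rate on
#' its type's markers, baseline rate elsewhere). Each observed count is
#' then zeroed independently with the truth's dropout probability, and
#' the `cell_type` annotation is re-derived from the observed counts by
#' assigning each cell to the type with the largest summed marker count
#' (ties broken at random under the seed).
#'
#' @param truth a [SimulationTruth-class].
#' @param nSamples samples for this condition (default 30).
#' @param cellsPerSample cells drawn per sample (default 1000).
#' @param seed integer seed.
#' @param condition condition label stored for every cell
#'   (default `"case"`).
#' @param samplePrefix prefix of the generated sample ids.
#' @return a `SingleCellExperiment` with `colData` columns `sample_id`,
#'   `condition`, `cell_type` (annotation inferred from expression) and
#'   `true_type` (generating type).
#' @export
simulateDataset <- function(truth, nSamples = 30L, cellsPerSample = 1000L,
                            seed = 1L, condition = "case",
                            samplePrefix = condition) {
  modeled <- cellTypes(truth)
  nBg <- length(truth@backgroundWeight)
  types <- c(modeled, sprintf("BG%02d", seq_len(nBg)))
  nT <- length(types)
  genes <- truth@geneIds
  lambda <- matrix(truth@baselineExpr, length(genes), nT,
                   dimnames = list(genes, types))
  for (k in types)
    lambda[truth@markers[[k]], k] <-
      if (k %in% names(truth@markerExpr)) truth@markerExpr[[k]] else
        truth@markerExpr[[1L]]
  statesM <- sampleStates(truth@model, nSamples,
                          seed = .deriveSeed(seed, 0L))
  old <- .safeSetSeed(.deriveSeed(seed, 1L))
  on.exit(.restoreSeed(old))
  blocks <- vector("list", nSamples)
  meta <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    eff <- ifelse(truth@polarity > 0, statesM[s, ], 1L - statesM[s, ])
    mu <- ifelse(eff == 1L, truth@fractionMap[, "high"],
                 truth@fractionMap[, "low"])
    f <- pmax(rnorm(length(modeled), mu, truth@fractionMap[, "sd"]), 0.001)
    if (nBg)
      f <- c(f, pmax(rnorm(nBg, truth@backgroundWeight,
                           truth@backgroundSd), 0.02))
    f <- f / sum(f)
    nk <- as.integer(rmultinom(1L, cellsPerSample, f))
    cellTypeVec <- rep(types, nk)
    m <- matrix(rpois(length(genes) * cellsPerSample,
                      lambda[, rep(seq_len(nT), nk)]),
                length(genes), cellsPerSample)
    blocks[[s]] <- m
    meta[[s]] <- data.frame(
      sample_id = sprintf("%s_s%02d", samplePrefix, s),
      condition = condition, true_type = cellTypeVec)
  }
  counts <- do.call(cbind, blocks)
  cd <- do.call(rbind, meta)
  if (truth@dropout > 0) {
    nz <- which(counts > 0)
    drop <- nz[runif(length(nz)) < truth@dropout]
    counts[drop] <- 0L
  }
  # annotation from observed expression: argmax of summed marker counts
  ind <- matrix(0, length(genes), nT, dimnames = list(genes, types))
  for (k in types) ind[truth@markers[[k]], k] <- 1
  score <- crossprod(ind, counts)            # types x cells
  jitter <- matrix(runif(length(score)) * 1e-3, nrow(score))
  cd$cell_type <- types[max.col(t(score + jitter))]
  rownames(counts) <- genes
  colnames(counts) <- sprintf("c%06d", seq_len(ncol(counts)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix")),
    colData = S4Vectors::DataFrame(sample_id = cd$sample_id,
                                   condition = cd$condition,
                                   cell_type = cd$cell_type,
                                   true_type = cd$true_type))
  colnames(sce) <- colnames(counts)
  sce
}

#' Simulate a two-condition dataset
#'
#' Convenience wrapper: the case condition follows the truth network, the
#' control condition an edge-free version of it (all types independent at
#' their marginal root probability), so every truth edge is a planted
#' differential interaction.
#'
#' @inheritParams simulateDataset
#' @param conditions labels for (control, case).
#' @return a single `SingleCellExperiment` with both conditions.
#' @export
simulateCaseControl <- function(truth, nSamples = 30L,
                                cellsPerSample = 1000L, seed = 1L,
                                conditions = c("control", "case")) {
  nullTruth <- truth
  nullModel <- fitCPTs(
    matrix(rep(0:1, length(cellTypes(truth))), 2L,
           dimnames = list(NULL, cellTypes(truth))),
    newDag(cellTypes(truth)), pseudocount = 0)
  nullTruth@model <- nullModel
  ctrl <- simulateDataset(nullTruth, nSamples, cellsPerSample,
                          seed = .deriveSeed(seed, 101L),
                          condition = conditions[[1L]])
  case <- simulateDataset(truth, nSamples, cellsPerSample,
                          seed = .deriveSeed(seed, 202L),
                          condition = conditions[[2L]])
  BiocGenerics::cbind(ctrl, case)
}

#' Score edge recovery against the simulation truth
#'
#' Thresholds the bootstrap edge counts and compares the resulting edge
#' set with the ground truth. By default the match is undirected (an edge
#' direction inside a Markov equivalence class is not identifiable);
#' `directionSensitive = TRUE` requires the exact direction. Accuracy is
#' true positives over ground-truth edges; precision is true positives
#' over predicted edges (1 by convention when nothing is predicted, with
#' `flagged = TRUE`).
#'
#' @param predicted an [EdgeCountTable-class].
#' @param truth a [SimulationTruth-class].
#' @param threshold minimum bootstrap count (default 20).
#' @param directionSensitive match edge directions (default FALSE).
#' @return list with `tp`, `fp`, `nPredicted`, `accuracy`, `precision`,
#'   `flagged`.
#' @export
evaluateRecovery <- function(predicted, truth, threshold = 20L,
                             directionSensitive = FALSE) {
  ct <- predicted@counts
  idx <- which(ct >= threshold, arr.ind = TRUE)
  predPairs <- cbind(rownames(ct)[idx[, 1L]], colnames(ct)[idx[, 2L]])
  truthPairs <- truth@model@dag@edges
  key <- function(m) {
    if (!nrow(m)) return(character(0))
    if (directionSensitive) paste(m[, 1L], m[, 2L], sep = "|")
    else paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]), sep = "|")
  }
  pk <- unique(key(predPairs))
  tk <- unique(key(truthPairs))
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  flagged <- length(pk) == 0L
  list(tp = tp, fp = fp, nPredicted = length(pk),
       accuracy = tp / length(tk),
       precision = if (flagged) 1 else tp / length(pk),
       flagged = flagged)
}

#' Recovery as a function of the dropout rate
#'
#' One full simulate / bootstrap / evaluate run per dropout rate, sharing
#' the truth network. Recovery is expected to decay with dropout, but only
#' as a trend over seeds, not per run.
#'
#' @param truth a [SimulationTruth-class] (its own dropout slot is
#'   ignored; `rates` is used instead).
#' @param rates dropout rates in \[0, 1).
#' @param seed integer seed.
#' @param nSamples,cellsPerSample,nIter,threshold,minCells pipeline sizes.
#' @return data.frame with one row per rate: `rate`, `tp`, `fp`,
#'   `accuracy`, `precision`.
#' @export
dropoutSweep <- function(truth, rates, seed = 1L, nSamples = 30L,
                         cellsPerSample = 300L, nIter = 100L,
                         threshold = 20L, minCells = 100) {
  rows <- lapply(rates, function(r) {
    tr <- truth
    tr@dropout <- r
    sce <- simulateDataset(tr, nSamples, cellsPerSample,
                           seed = .deriveSeed(seed, round(1000 * r)))
    ect <- bootstrapEdges(sce, "case", nIter = nIter, minCells = minCells,
                          seed = .deriveSeed(seed, 5000L + round(1000 * r)))
    ev <- evaluateRecovery(ect, truth, threshold = threshold)
    data.frame(rate = r, tp = ev$tp, fp = ev$fp, accuracy = ev$accuracy,
               precision = ev$precision)
  })
  do.call(rbind, rows)
}

#' Serialize a simulation truth
#'
#' Writes the ground-truth edge list and the generator parameters as
#' plain-text files next to the dataset.
#'
#' @param truth a [SimulationTruth-class].
#' @param dir output directory.
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(as.data.frame(truth@model@dag@edges),
            file.path(dir, "truth_edges.tsv"))
  yaml::write_yaml(list(
    nTypes = length(cellTypes(truth)),
    fractionMap = as.data.frame(truth@fractionMap),
    baselineExpr = truth@baselineExpr, markerExpr = truth@markerExpr,
    dropout = truth@dropout, nGenes = length(truth@geneIds)),
    file.path(dir, "truth_params.yaml"))
  invisible(dir)
}
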