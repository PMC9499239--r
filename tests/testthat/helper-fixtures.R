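# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# Minimal annotated expression object: counts is genes x cells.
makeTinySCE <- function(counts, sample_id, condition, cell_type,
                        genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(counts)))
  rownames(counts) <- genes
  colnames(counts) <- sprintf("c%d", seq_len(ncol(counts)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix")),
    colData = S4Vectors::DataFrame(sample_id = sample_id,
                                   condition = condition,
                                   cell_type = cell_type))
}

# Label-only dataset: one cell per row of the given composition counts.
makeLabelSCE <- function(countTable, conditions) {
  sample_id <- character(0); cell_type <- character(0); condition <- character(0)
  for (s in rownames(countTable)) {
    for (ct in colnames(countTable)) {
      n <- countTable[s, ct]
      sample_id <- c(sample_id, rep(s, n))
      cell_type <- c(cell_type, rep(ct, n))
      condition <- c(condition, rep(conditions[[s]], n))
    }
  }
  counts <- matrix(1, 2, length(sample_id))
  makeTinySCE(counts, sample_id, condition, cell_type)
}

# EdgeCountTable straight from a named count list ("A->B" = count).
makeCountTable <- function(types, counts, nIter = 100L,
                           condition = "case") {
  m <- matrix(0L, length(types), length(types),
              dimnames = list(types, types))
  for (key in names(counts)) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    m[ft[1], ft[2]] <- as.integer(counts[[key]])
  }
  new("EdgeCountTable", counts = m, nIter = as.integer(nIter),
      condition = condition)
}

# Enumerate all 25 DAGs on 3 labelled nodes (by brute force over the
# 3^3 = 27 orientation patterns of the three possible undirected pairs,
# dropping the two cyclic triangles).
allThreeNodeDags <- function(nodes = c("A", "B", "C")) {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    e <- matrix(character(0), 0, 2)
    states <- c(s1, s2, s3)
    for (p in seq_along(pairs)) {
      if (states[p] == 1L)
        e <- rbind(e, nodes[pairs[[p]]])
      if (states[p] == 2L)
        e <- rbind(e, rev(nodes[pairs[[p]]]))
    }
    dag <- tryCatch(newDag(nodes, e), error = function(err) NULL)
    if (!is.null(dag)) out[[length(out) + 1L]] <- dag
  }
  out
}

# Planted-effect ligand-target dataset: sender cells shift `nActive`
# ligand genes between conditions, receiver target genes respond through
# the regulatory-potential matrix. Returns the SCE, the potential matrix
# and the active ligand names.
makeLtrToy <- function(nLigands = 12L, nTargets = 80L, nActive = 3L,
                       cellsPer = 40L, effect = 2, noise = 0.1,
                       seed = 1L) {
  set.seed(seed)
  ligands <- sprintf("L%02d", seq_len(nLigands))
  targetsv <- sprintf("T%03d", seq_len(nTargets))
  I <- matrix(runif(nTargets * nLigands), nTargets, nLigands,
              dimnames = list(targetsv, ligands))
  active <- sample(ligands, nActive)
  alphaStar <- setNames(numeric(nLigands), ligands)
  alphaStar[active] <- 1
  base <- 2
  ligCase <- setNames(rep(base, nLigands), ligands)
  ligCase[active] <- base * exp(effect)      # lfc ~ `effect` for active
  # receiver targets respond: case mean = base * exp(I %*% (lfc * alpha))
  lfc <- log((ligCase + 1) / (base + 1))
  shift <- as.numeric(I %*% (lfc * alphaStar))
  tgCase <- base * exp(shift)
  genes <- c(ligands, targetsv)
  mkCells <- function(type, cond, mu) {
    m <- matrix(rpois(length(genes) * cellsPer,
                      rep(mu, cellsPer) * exp(rnorm(length(genes) * cellsPer,
                                                    0, noise))),
                length(genes), cellsPer)
    list(m = m, type = rep(type, cellsPer), cond = rep(cond, cellsPer))
  }
  muS_ctrl <- c(rep(base, nLigands), rep(base, nTargets))
  muS_case <- c(ligCase, rep(base, nTargets))
  muR_ctrl <- c(rep(base, nLigands), rep(base, nTargets))
  muR_case <- c(rep(base, nLigands), tgCase)
  blocks <- list(mkCells("sender", "ctrl", muS_ctrl),
                 mkCells("sender", "case", muS_case),
                 mkCells("receiver", "ctrl", muR_ctrl),
                 mkCells("receiver", "case", muR_case))
  counts <- do.call(cbind, lapply(blocks, `[[`, "m"))
  sce <- makeTinySCE(counts,
                     sample_id = rep("s1", ncol(counts)),
                     condition = unlist(lapply(blocks, `[[`, "cond")),
                     cell_type = unlist(lapply(blocks, `[[`, "type")),
                     genes = genes)
  list(sce = sce, ltm = newLigandTargetMatrix(I), active = active,
       alphaStar = alphaStar)
}
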