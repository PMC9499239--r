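# Pipeline orchestration: a flat YAML-backed config plus one command per
# stage. Every output file carries a header comment with the config hash
# and seed, so a rerun with an identical config is byte-identical.

#' Default pipeline configuration
#'
#' Returns the full parameter list with the pipeline defaults: abundance
#' filter 100 cells, 100 bootstrap iterations on 80% cell subsamples,
#' differential threshold 20, five CV folds, independence tests at 0.003.
#'
#' @return named list.
#' @export
defaultConfig <- function() {
  list(
    expression = NULL, cells = NULL, genes = NULL,
    newExpression = NULL, newCells = NULL, newGenes = NULL,
    ligandTarget = NULL, renameMap = NULL, outDir = "intercellbn_out",
    caseCondition = NULL, controlCondition = NULL,
    minCells = 100, nIter = 100, cellFrac = 0.8, threshold = 20,
    nFolds = 5, alpha = 0.003, maxCondSize = 3, nPerm = 100,
    strategy = "gmm", lfcMode = "lfc", permutationAxis = "types",
    directionSensitive = FALSE, pseudocount = 1,
    nTypes = 10, nEdges = 6, nSamples = 30, cellsPerSample = 300,
    dropout = 0, seed = 1)
}

#' Read a pipeline configuration
#'
#' Loads a YAML config file (if given) on top of [defaultConfig()], then
#' applies explicit overrides. Unknown keys are rejected.
#'
#' @param path optional YAML file.
#' @param overrides named list applied last (e.g. parsed CLI flags).
#' @return named config list.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  apply_ <- function(cfg, vals, src) {
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad))
      stop("unknown config key(s) in ", src, ": ",
           paste(bad, collapse = ", "))
    cfg[names(vals)] <- vals
    cfg
  }
  if (!is.null(path)) cfg <- apply_(cfg, yaml::read_yaml(path), path)
  if (length(overrides)) cfg <- apply_(cfg, overrides, "overrides")
  cfg
}

#' Write a configuration file
#'
#' @param config config list.
#' @param path output YAML path. Round-trips losslessly through
#'   [readPipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

# fingerprint of the scientific parameters; the output location is not
# part of the identity of a run
.configStamp <- function(config) {
  config$outDir <- NULL
  sprintf("config %s seed %d", .fnv1a(yaml::as.yaml(config)),
          as.integer(config$seed))
}

.loadFromConfig <- function(config, which = "expression") {
  m <- config[[which]]
  cellsKey <- if (which == "expression") "cells" else "newCells"
  genesKey <- if (which == "expression") "genes" else "newGenes"
  if (is.null(m)) stop("network stage: config key '", which, "' not set")
  loadExpression(m, config[[cellsKey]], config[[genesKey]],
                 renameMap = config$renameMap)
}

.twoConditions <- function(sce, config) {
  conds <- unique(SummarizedExperiment::colData(sce)$condition)
  case <- config$caseCondition
  ctrl <- config$controlCondition
  if (is.null(case) || is.null(ctrl)) {
    if (length(conds) != 2L)
      stop("dataset has ", length(conds),
           " conditions; set caseCondition/controlCondition")
    ctrl <- sort(conds)[[1L]]; case <- sort(conds)[[2L]]
  }
  c(control = ctrl, case = case)
}

#' Network stage: bootstrap networks per condition and differential edges
#'
#' Runs io -> fractions -> discretization -> structure learning under the
#' bootstrap for both conditions and writes per-condition edge count
#' tables, the differential edge table and per-condition DOT graphs of
#' the edges at or above the threshold.
#'
#' @param config config list, see [defaultConfig()].
#' @return invisibly, a list with both [EdgeCountTable-class]s and the
#'   differential data.frame.
#' @export
cmdNetwork <- function(config) {
  sce <- .loadFromConfig(config)
  conds <- .twoConditions(sce, config)
  stamp <- .configStamp(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  run <- function(cond, offs)
    bootstrapEdges(sce, cond, nIter = config$nIter,
                   cellFrac = config$cellFrac, minCells = config$minCells,
                   alpha = config$alpha, maxCondSize = config$maxCondSize,
                   strategy = config$strategy,
                   seed = .deriveSeed(config$seed, offs))
  tabs <- list(case = run(conds[["case"]], 1L),
               control = run(conds[["control"]], 2L))
  for (nm in names(tabs)) {
    writeEdgeTable(tabs[[nm]],
                   file.path(config$outDir,
                             sprintf("edge_counts_%s.tsv", conds[[nm]])),
                   header = stamp)
    keep <- which(tabs[[nm]]@counts >= config$threshold, arr.ind = TRUE)
    dag <- newDag(rownames(tabs[[nm]]@counts),
                  cbind(rownames(tabs[[nm]]@counts)[keep[, 1L]],
                        colnames(tabs[[nm]]@counts)[keep[, 2L]]))
    dg <- tryCatch(dag, error = function(e) NULL)
    if (!is.null(dg))
      writeDag(dg, file.path(config$outDir,
                             sprintf("network_%s.dot", conds[[nm]])),
               format = "dot")
  }
  diff <- differentialEdges(tabs$case, tabs$control, config$threshold)
  .writeTsv(diff, file.path(config$outDir, "differential_edges.tsv"),
            header = stamp)
  invisible(list(case = tabs$case, control = tabs$control,
                 differential = diff))
}

#' Ligand stage: LTR fits, controls and the joint agreement table
#'
#' For every sender/receiver pair in `pairsFile` (TSV with columns `from`,
#' `to` and optionally `count`, typically the differential table), fits
#' the paracrine LTR model, the autocrine control and the shuffled-matrix
#' control, writes one ranked-ligand TSV per pair and a summary table,
#' and, when counts are available, the joint agreement of bootstrap edge
#' score and LTR correlation.
#'
#' @param config config list; needs `ligandTarget` set.
#' @param pairsFile path to the pair table.
#' @return invisibly, the summary data.frame.
#' @export
cmdLigands <- function(config, pairsFile) {
  sce <- .loadFromConfig(config)
  conds <- .twoConditions(sce, config)
  ltm <- loadLigandTargetMatrix(config$ligandTarget)
  pairs <- .readTable(pairsFile)
  stamp <- .configStamp(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    from <- pairs$from[[i]]; to <- pairs$to[[i]]
    fit <- tryCatch(
      ltrForPair(sce, ltm, from, to, conds[["case"]], conds[["control"]],
                 mode = config$lfcMode, pseudocount = config$pseudocount,
                 nFolds = config$nFolds,
                 seed = .deriveSeed(config$seed, 100L + i)),
      error = function(e) {
        message("pair ", from, " -> ", to, " skipped: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    fits[[.pairKey(from, to)]] <- fit
    auto <- autocrineControl(sce, ltm, to, conds[["case"]],
                             conds[["control"]], mode = config$lfcMode,
                             pseudocount = config$pseudocount,
                             nFolds = config$nFolds,
                             seed = .deriveSeed(config$seed, 200L + i))
    rnd <- randomMatrixControl(
      newLigandTargetMatrix(ltm@potential[attr(fit, "targets"), ,
                                          drop = FALSE]),
      conditionLFC(sce, to, conds[["case"]], conds[["control"]],
                   config$pseudocount)[attr(fit, "targets")],
      attr(fit, "L"), nShuffles = 5L, nFolds = config$nFolds,
      seed = .deriveSeed(config$seed, 300L + i))
    if (!isDegenerate(fit))
      .writeTsv(attr(fit, "ranking"),
                file.path(config$outDir,
                          sprintf("ligands_%s_to_%s.tsv", from, to)),
                header = stamp)
    rows[[length(rows) + 1L]] <- data.frame(
      from = from, to = to,
      degenerate = isDegenerate(fit),
      mean_pearson = meanPearson(fit),
      autocrine_pearson = meanPearson(auto),
      random_frac_degenerate = rnd$fracDegenerate)
  }
  summary <- do.call(rbind, rows)
  if (is.null(summary)) summary <- data.frame()
  .writeTsv(summary, file.path(config$outDir, "ltr_summary.tsv"),
            header = stamp)
  if ("count" %in% colnames(pairs)) {
    agr <- bnLtrAgreement(pairs, fits, threshold = config$threshold)
    .writeTsv(agr$table, file.path(config$outDir, "bn_ltr_joint.tsv"),
              header = paste(stamp, "| r =",
                             formatC(agr$r, digits = 4, format = "g")))
  }
  invisible(summary)
}

#' Simulation stage: write a synthetic case-control dataset plus truth
#'
#' @param config config list (`nTypes`, `nEdges`, `nSamples`,
#'   `cellsPerSample`, `dropout`, `seed`).
#' @return invisibly, the output directory.
#' @export
cmdSimulate <- function(config) {
  truth <- makeTruth(nTypes = config$nTypes, nEdges = config$nEdges,
                     seed = config$seed, dropout = config$dropout)
  sce <- simulateCaseControl(truth, nSamples = config$nSamples,
                             cellsPerSample = config$cellsPerSample,
                             seed = config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(sce, config$outDir)
  writeTruth(truth, config$outDir)
  writePipelineConfig(config, file.path(config$outDir, "config.yaml"))
  invisible(config$outDir)
}

#' Validation stage: recovery metrics of the full loop on simulated data
#'
#' Simulates one dataset from a fresh truth, runs the bootstrap pipeline
#' on the case condition and prints/writes the recovery metrics row
#' (true/false positives, accuracy, precision at the configured
#' threshold).
#'
#' @param config config list.
#' @return invisibly, the one-row metrics data.frame.
#' @export
cmdValidate <- function(config) {
  truth <- makeTruth(nTypes = config$nTypes, nEdges = config$nEdges,
                     seed = config$seed, dropout = config$dropout)
  sce <- simulateDataset(truth, nSamples = config$nSamples,
                         cellsPerSample = config$cellsPerSample,
                         seed = .deriveSeed(config$seed, 7L))
  ect <- bootstrapEdges(sce, "case", nIter = config$nIter,
                        cellFrac = config$cellFrac,
                        minCells = config$minCells, alpha = config$alpha,
                        strategy = config$strategy,
                        seed = .deriveSeed(config$seed, 8L))
  ev <- evaluateRecovery(ect, truth, threshold = config$threshold,
                         directionSensitive = config$directionSensitive)
  row <- data.frame(dropout = config$dropout, tp = ev$tp, fp = ev$fp,
                    accuracy = ev$accuracy, precision = ev$precision)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(row, file.path(config$outDir, "recovery_metrics.tsv"),
            header = .configStamp(config))
  print(row)
  invisible(row)
}

#' Enhancement stage: does an added dataset reinforce the original edges?
#'
#' @param config config list; `expression`/`cells`/`genes` point at the
#'   base dataset and `newExpression`/`newCells`/`newGenes` at the added
#'   one.
#' @return invisibly, the enhancement data.frame.
#' @export
cmdEnhance <- function(config) {
  base <- .cellLabels(.loadFromConfig(config))
  newd <- .cellLabels(.loadFromConfig(config, "newExpression"))
  conds <- sort(unique(base$condition))
  if (length(conds) != 2L) stop("base dataset must have two conditions")
  orig <- .labelBootstrapPair(base, conds, config$nIter, config$cellFrac,
                              config$minCells,
                              seed = .deriveSeed(config$seed, 31L))
  comb <- .labelBootstrapPair(rbind(base, newd), conds, config$nIter,
                              config$cellFrac, config$minCells,
                              seed = .deriveSeed(config$seed, 32L))
  enh <- enhancementAnalysis(orig, comb, config$threshold)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(enh, file.path(config$outDir, "enhancement.tsv"),
            header = .configStamp(config))
  invisible(enh)
}

#' Permutation stage: significance of the cross-dataset enhancement
#'
#' @param config config list; dataset keys as in [cmdEnhance()].
#' @return invisibly, the [permutationTest()] result list.
#' @export
cmdPermtest <- function(config) {
  base <- .loadFromConfig(config)
  newd <- .loadFromConfig(config, "newExpression")
  res <- permutationTest(base, newd, nPerm = config$nPerm,
                         threshold = config$threshold,
                         nIter = config$nIter,
                         axis = config$permutationAxis,
                         minCells = config$minCells,
                         cellFrac = config$cellFrac, seed = config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(data.frame(p = res$p, observed = res$observed),
            file.path(config$outDir, "permutation_test.tsv"),
            header = .configStamp(config))
  invisible(res)
}
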