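# Restrict-maximize structure learning: Hiton-PC candidate screening
# (restrict) followed by BIC hill climbing constrained to the screened
# skeleton (maximize).

#' Hiton-PC candidate parents-and-children screening
#'
#' Constraint-based restrict phase. For each target node, the other nodes
#' are ranked by marginal association (G-squared test on the 2x2 table) and
#' admitted greedily; after each admission, any admitted node that is
#' conditionally independent of the target given some subset of the other
#' admitted nodes (subsets up to `maxCondSize`) is removed. The per-node
#' sets are then symmetrized by intersection: the pair a-b survives only if
#' each node is in the other's set. Tests whose 2x2(xZ) table has any
#' expected count below 1 are inconclusive and never used to admit (at the
#' marginal step) or to remove (at the conditional step) a node.
#'
#' @param data a [BinaryMatrix-class] or 0/1 matrix.
#' @param alpha significance level of the independence tests (default
#'   0.003). Composition studies have tens of samples and dozens of
#'   candidate pairs, and chance associations among the fixed per-sample
#'   states survive cell-level bootstrapping, so the screening level is
#'   the false-edge control of the whole pipeline; 0.003 keeps the
#'   expected number of persistent chance skeleton links per network
#'   well below one while direct dependencies of realistic strength
#'   pass comfortably.
#' @param maxCondSize largest conditioning-set size (default 3).
#' @param elimAlpha threshold for *declaring* conditional independence in
#'   the elimination step (default: `alpha`). Admission and elimination
#'   play asymmetric roles: a candidate should only be admitted when its
#'   marginal association is clearly real (small `alpha`), but it should
#'   be dropped as soon as some conditioning set renders it *plausibly*
#'   independent; setting `elimAlpha` above `alpha` makes the elimination
#'   correspondingly more aggressive against indirect neighbours.
#' @return symmetric logical matrix (nodes x nodes): the undirected
#'   candidate skeleton.
#' @export
hitonPC <- function(data, alpha = 0.003, maxCondSize = 3L,
                    elimAlpha = alpha) {
  D <- .stateMatrix(data)
  n <- ncol(D)
  nodes <- colnames(D)
  const <- apply(D, 2L, function(x) length(unique(x)) == 1L)
  if (any(const))
    warning("constant column(s) get an empty candidate set: ",
            paste(nodes[const], collapse = ", "))
  pc <- vector("list", n)
  for (t in seq_len(n)) {
    others <- setdiff(seq_len(n), t)
    marg <- lapply(others, function(o) .g2Test(D[, o], D[, t]))
    keep <- vapply(marg, function(g) g$valid && g$p < alpha, logical(1))
    cand <- others[keep][order(-vapply(marg[keep], `[[`, numeric(1),
                                       "stat"))]
    cur <- integer(0)
    for (cnd in cand) {
      cur <- c(cur, cnd)
      # elimination: drop any member separable from t given a subset of
      # the rest of the current set
      repeat {
        dropped <- FALSE
        for (x in cur) {
          rest <- setdiff(cur, x)
          if (.separable(D, x, t, rest, elimAlpha, maxCondSize)) {
            cur <- rest
            dropped <- TRUE
            break
          }
        }
        if (!dropped) break
      }
    }
    pc[[t]] <- cur
  }
  skel <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (t in seq_len(n))
    for (x in pc[[t]])
      if (t %in% pc[[x]]) skel[t, x] <- skel[x, t] <- TRUE
  skel
}

# TRUE if some conditioning subset Z of `pool` (|Z| <= maxCondSize, Z may
# be empty) renders x and t independent at level alpha, by a valid G^2 test
.separable <- function(D, x, t, pool, alpha, maxCondSize) {
  for (k in 0:min(length(pool), maxCondSize)) {
    subsets <- if (k == 0L) list(integer(0)) else
      utils::combn(pool, k, simplify = FALSE)
    for (z in subsets) {
      g <- .g2Test(D[, x], D[, t],
                   if (length(z)) D[, z, drop = FALSE] else NULL)
      if (g$valid && g$p >= alpha) return(TRUE)
    }
  }
  FALSE
}

#' BIC hill climbing over a candidate skeleton
#'
#' Greedy best-first search from the empty graph. At each step every legal
#' move is scored: add an edge (only between skeleton pairs, only if
#' acyclicity is preserved), delete an existing edge, or reverse one. The
#' single move with the largest positive BIC improvement is applied; equal
#' improvements are broken lexicographically by (source, target,
#' move-type), so the search is fully deterministic. When no single move
#' improves the score, one composite move is considered: adding a *pair*
#' of parents to a common child (both within the skeleton). This is the
#' v-structure escape — two marginally independent parents of a collider
#' give no single-edge foothold, yet the joint addition can raise the
#' score — and it is evaluated with one family score, so it costs
#' next to nothing. Each accepted move, single or composite, strictly
#' increases the BIC. Stops when no move improves the score or `maxIter`
#' moves were applied.
#'
#' @param data a [BinaryMatrix-class] or 0/1 matrix.
#' @param skeleton symmetric logical matrix from [hitonPC()]; `NULL` means
#'   the complete skeleton (unrestricted search).
#' @param maxIter maximum number of accepted moves (default 1000).
#' @param debug if TRUE, every accepted incremental score is cross-checked
#'   against a full recomputation.
#' @return a [Dag-class].
#' @export
hillClimb <- function(data, skeleton = NULL, maxIter = 1000L,
                      debug = FALSE) {
  D <- .stateMatrix(data)
  n <- ncol(D)
  nodes <- colnames(D)
  logN <- log(nrow(D))
  if (is.null(skeleton)) {
    skeleton <- matrix(TRUE, n, n, dimnames = list(nodes, nodes)) &
      !diag(n)
  }
  skeleton <- skeleton[nodes, nodes]
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  pa <- rep(list(integer(0)), n)
  nodeScore <- vapply(seq_len(n), function(q) .familyBic(D, q, integer(0),
                                                         logN), numeric(1))
  ord <- order(nodes)          # lexicographic sweep order
  eps <- 1e-9
  moves <- 0L
  repeat {
    best <- list(delta = eps)
    for (u in ord) for (v in ord) {
      if (u == v) next
      if (!adj[u, v] && !adj[v, u] && skeleton[u, v]) {
        if (!.reachable(adj, v, u)) {
          delta <- .familyBic(D, v, c(pa[[v]], u), logN) - nodeScore[v]
          if (delta > best$delta)
            best <- list(delta = delta, type = "add", u = u, v = v)
        }
      }
      if (adj[u, v]) {
        delta <- .familyBic(D, v, setdiff(pa[[v]], u), logN) - nodeScore[v]
        if (delta > best$delta)
          best <- list(delta = delta, type = "delete", u = u, v = v)
        adj2 <- adj; adj2[u, v] <- FALSE
        if (!.reachable(adj2, u, v)) {
          delta <- (.familyBic(D, v, setdiff(pa[[v]], u), logN) -
                      nodeScore[v]) +
                   (.familyBic(D, u, c(pa[[u]], v), logN) - nodeScore[u])
          if (delta > best$delta)
            best <- list(delta = delta, type = "reverse", u = u, v = v)
        }
      }
    }
    if (is.null(best$type)) {
      # v-structure escape: give a common child two parents at once,
      # each taken in by an edge addition or a reversal
      pair <- NULL
      for (v in ord) {
        # neighbours that could become parents of v: not already parents,
        # connected in the skeleton (an existing v -> u edge implies so)
        nb <- which((skeleton[, v] | adj[v, ]) & !adj[, v])
        if (length(nb) < 2L) next
        for (j in seq_along(nb)) for (k in seq_len(j - 1L)) {
          u <- nb[k]; w <- nb[j]
          adj2 <- adj
          adj2[v, u] <- adj2[v, w] <- FALSE     # undo reversals first
          if (.reachable(adj2, v, u) || .reachable(adj2, v, w)) next
          delta <- .familyBic(D, v, c(pa[[v]], u, w), logN) - nodeScore[v]
          for (x in c(u, w)) if (adj[v, x])
            delta <- delta +
              .familyBic(D, x, setdiff(pa[[x]], v), logN) - nodeScore[x]
          if (delta > eps && (is.null(pair) || delta > pair$delta))
            pair <- list(delta = delta, v = v, u = u, w = w)
        }
      }
      if (is.null(pair)) break
      v <- pair$v
      for (x in c(pair$u, pair$w)) {
        if (adj[v, x]) {                        # reversal
          adj[v, x] <- FALSE
          pa[[x]] <- setdiff(pa[[x]], v)
          nodeScore[x] <- .familyBic(D, x, pa[[x]], logN)
        }
        adj[x, v] <- TRUE
        pa[[v]] <- c(pa[[v]], x)
      }
      nodeScore[v] <- .familyBic(D, v, pa[[v]], logN)
      if (debug) {
        full <- bicScore(D, .adjToDag(nodes, adj))
        stopifnot(abs(full - sum(nodeScore)) < 1e-8)
      }
      moves <- moves + 1L
      if (moves >= maxIter) break
      next
    }
    u <- best$u; v <- best$v
    if (best$type == "add") {
      adj[u, v] <- TRUE
      pa[[v]] <- c(pa[[v]], u)
      nodeScore[v] <- .familyBic(D, v, pa[[v]], logN)
    } else if (best$type == "delete") {
      adj[u, v] <- FALSE
      pa[[v]] <- setdiff(pa[[v]], u)
      nodeScore[v] <- .familyBic(D, v, pa[[v]], logN)
    } else {
      adj[u, v] <- FALSE; adj[v, u] <- TRUE
      pa[[v]] <- setdiff(pa[[v]], u)
      pa[[u]] <- c(pa[[u]], v)
      nodeScore[v] <- .familyBic(D, v, pa[[v]], logN)
      nodeScore[u] <- .familyBic(D, u, pa[[u]], logN)
    }
    if (debug) {
      full <- bicScore(D, .adjToDag(nodes, adj))
      stopifnot(abs(full - sum(nodeScore)) < 1e-8)
    }
    moves <- moves + 1L
    if (moves >= maxIter) break
  }
  .adjToDag(nodes, adj)
}

.adjToDag <- function(nodes, adj) {
  idx <- which(adj, arr.ind = TRUE)
  newDag(nodes, cbind(nodes[idx[, 1L]], nodes[idx[, 2L]]))
}

#' Learn a cell type network from binary abundance states
#'
#' The full restrict-maximize scheme: [hitonPC()] screening followed by
#' [hillClimb()] restricted to the screened skeleton. Deterministic for
#' fixed data and parameters.
#'
#' @inheritParams hitonPC
#' @param maxIter passed to [hillClimb()].
#' @return a [Dag-class].
#' @examples
#' set.seed(7)
#' a <- rbinom(60, 1, 0.5)
#' b <- ifelse(runif(60) < 0.9, a, 1 - a)
#' d <- cbind(A = a, B = b, C = rbinom(60, 1, 0.5))
#' edges(learnNetwork(d))
#' @export
learnNetwork <- function(data, alpha = 0.003, maxCondSize = 3L,
                         elimAlpha = alpha, maxIter = 1000L) {
  skel <- hitonPC(data, alpha = alpha, maxCondSize = maxCondSize,
                  elimAlpha = elimAlpha)
  hillClimb(data, skeleton = skel, maxIter = maxIter)
}
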