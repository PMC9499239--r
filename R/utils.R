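# Internal helpers shared across modules.

# Acyclicity by repeated removal of sink-free... (Kahn's algorithm on the
# adjacency list). `edges` is a 2-column character matrix.
.isAcyclic <- function(nodes, edges) {
  if (!nrow(edges)) return(TRUE)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges[, 2L], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  out <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(nodes)
}

# TRUE if `to` is reachable from `from` in the adjacency matrix `adj`
# (logical, nodes x nodes). Used for cycle checks in hill climbing.
.reachable <- function(adj, from, to) {
  if (from == to) return(TRUE)
  n <- nrow(adj)
  visited <- logical(n)
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (visited[[v]]) next
    visited[[v]] <- TRUE
    nxt <- which(adj[v, ] & !visited)
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt)
  }
  FALSE
}

# Deterministic stream of per-iteration seeds below 2^31, spread out so
# that nearby master seeds do not share iteration seeds.
.deriveSeed <- function(seed, i) {
  as.integer((as.double(seed %% 49999L) * 40009 + as.double(i) * 7919 +
                12345) %% 2147483587)
}

# G^2 (likelihood-ratio) test of independence between two binary vectors,
# optionally conditioned on a set of binary columns `z` (matrix or NULL).
# Returns stat, df, p and `valid` (FALSE when any expected count in a
# contributing stratum falls below 0.5, in which case the test is
# inconclusive). The floor keeps the asymptotic test away from degenerate
# tables while still allowing the moderately sparse strata that arise
# when conditioning on a strong neighbour at a few dozen samples - those
# are exactly the tests that must run for indirect edges to be screened
# out.
.g2Test <- function(x, y, z = NULL) {
  if (is.null(z) || ncol(as.matrix(z)) == 0L) {
    strata <- rep.int(0L, length(x))
    nstr <- 1L
  } else {
    z <- as.matrix(z)
    strata <- as.integer(z %*% 2L^(seq_len(ncol(z)) - 1L))
    nstr <- 2L^ncol(z)
  }
  stat <- 0
  valid <- TRUE
  for (s in unique(strata)) {
    idx <- strata == s
    n <- sum(idx)
    if (n == 0L) next
    o <- matrix(0, 2L, 2L)
    tt <- table(factor(x[idx], levels = 0:1), factor(y[idx], levels = 0:1))
    o[] <- as.numeric(tt)
    e <- outer(rowSums(o), colSums(o)) / n
    if (any(e < 0.5)) { valid <- FALSE; next }
    nz <- o > 0
    stat <- stat + 2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  df <- nstr
  list(stat = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE), valid = valid)
}

# Write a data.frame as TSV with a provenance comment header.
.writeTsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FNV-1a hash of a character scalar, hex string; used to stamp outputs
# with a config fingerprint.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Ordered-pair key used in edge tallies.
.pairKey <- function(from, to) paste(from, to, sep = " -> ")
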