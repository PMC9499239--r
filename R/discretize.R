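# Two-component Gaussian mixture discretization of cell type fractions.
#
# Each cell type's per-sample fraction vector is binarized independently:
# an EM-fitted two-component univariate mixture defines a type-specific
# cutoff, samples above it get state 1 (high abundance). The number of 0s
# and 1s per type is unconstrained and may be heavily skewed.

.VAR_FLOOR <- 1e-8

#' Fit a univariate two-component Gaussian mixture by EM
#'
#' Maximum-likelihood fit of \eqn{\pi_0 N(\mu_0,\sigma_0^2) + \pi_1
#' N(\mu_1,\sigma_1^2)} to a numeric vector via expectation-maximization.
#' Components are reported in increasing-mean order. Initialization is a
#' k-means++-style two-center draw on the values under the given seed; a
#' variance floor of 1e-8 keeps components non-singular. The full
#' log-likelihood trace is returned so callers can assert the EM ascent
#' property.
#'
#' @param values numeric vector, length >= 2.
#' @param maxIter maximum EM iterations (default 500).
#' @param tol convergence threshold on the log-likelihood increase
#'   (default 1e-4).
#' @param seed integer seed for the initialization draw.
#' @param maxSdRatio upper bound on the ratio of the two component
#'   standard deviations (default `Inf`, i.e. free per-component
#'   variances as in the plain mixture). With a few dozen points a free
#'   mixture can prefer splitting off a tight sub-cluster of one regime
#'   over cutting the gap between the regimes (it pays for the split with
#'   an extreme variance ratio); bounding the ratio forbids those
#'   degenerate solutions while still allowing the moderate
#'   heteroscedasticity real clusters have. The constrained M-step
#'   maximizes the expected log-likelihood on the boundary when the free
#'   estimate violates the bound, so EM ascent is preserved.
#' @return a list of class `gmm2` with elements `weights`, `means`, `sds`
#'   (each length 2, low-mean component first), `loglik`, `trace`,
#'   `converged`, `iterations`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(20, 0.1, 0.01), rnorm(20, 0.5, 0.01))
#' fit <- fitGMM2(x, seed = 1)
#' fit$means
#' @export
fitGMM2 <- function(values, maxIter = 500, tol = 1e-4, seed = 1L,
                    maxSdRatio = Inf) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (diff(range(values)) == 0)
    stop("degenerate input: all values identical; ",
         "use the midpoint strategy instead")
  # k-means++-style init: first center uniform, second weighted by squared
  # distance to the first.
  old <- .safeSetSeed(seed)
  on.exit(.restoreSeed(old))
  c1 <- values[sample.int(length(values), 1L)]
  d2 <- (values - c1)^2
  c2 <- values[sample.int(length(values), 1L, prob = d2 / sum(d2))]
  mu <- sort(c(c1, c2))
  s0 <- max(sd(values) / 2, sqrt(.VAR_FLOOR))
  sg <- c(s0, s0)
  pi1 <- c(0.5, 0.5)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    # E step (log-space for stability)
    lp <- cbind(log(pi1[1L]) + dnorm(values, mu[1L], sg[1L], log = TRUE),
                log(pi1[2L]) + dnorm(values, mu[2L], sg[2L], log = TRUE))
    m <- pmax(lp[, 1L], lp[, 2L])
    lse <- m + log(exp(lp[, 1L] - m) + exp(lp[, 2L] - m))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(prev) && ll - prev < tol) { converged <- TRUE; break }
    prev <- ll
    r2 <- exp(lp[, 2L] - lse)
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-12 || n2 < 1e-12)
      stop("degenerate input: one mixture component vanished; ",
           "use the midpoint strategy instead")
    pi1 <- c(n1, n2) / length(values)
    mu <- c(sum(r1 * values) / n1, sum(r2 * values) / n2)
    S1 <- sum(r1 * (values - mu[1L])^2)
    S2 <- sum(r2 * (values - mu[2L])^2)
    v1 <- S1 / n1; v2 <- S2 / n2
    R2 <- maxSdRatio^2
    if (is.finite(maxSdRatio) && max(v1, v2) > R2 * min(v1, v2)) {
      # constrained maximizer lies on the boundary sd_wide = R * sd_narrow
      if (v1 > v2) {
        v2 <- (S1 / R2 + S2) / (n1 + n2); v1 <- R2 * v2
      } else {
        v1 <- (S2 / R2 + S1) / (n1 + n2); v2 <- R2 * v1
      }
    }
    sg <- sqrt(pmax(c(v1, v2), .VAR_FLOOR))
  }
  ord <- order(mu)
  structure(list(weights = pi1[ord], means = mu[ord], sds = sg[ord],
                 loglik = trace[length(trace)], trace = trace,
                 converged = converged, iterations = iter),
            class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf(paste0("2-component Gaussian mixture: weights (%.3f, %.3f), ",
                     "means (%.4g, %.4g), sds (%.3g, %.3g)\n"),
              x$weights[1L], x$weights[2L], x$means[1L], x$means[2L],
              x$sds[1L], x$sds[2L]))
  cat(sprintf("log-likelihood %.4f after %d iterations (%sconverged)\n",
              x$loglik, x$iterations, if (x$converged) "" else "not "))
  invisible(x)
}

# Cutoff between the two components: the point in [mu0, mu1] where the
# posterior flips. With unequal variances the raw posterior-argmax rule can
# be non-monotone in the value (the far tails flip back to the wide
# component); a single cutoff between the means is enforced instead, which
# matches the intended "all samples below the cutoff are 0" semantics.
.gmm2Cutoff <- function(params) {
  mu <- params$means; sg <- params$sds; w <- params$weights
  g <- function(x)
    (log(w[2L]) + dnorm(x, mu[2L], sg[2L], log = TRUE)) -
      (log(w[1L]) + dnorm(x, mu[1L], sg[1L], log = TRUE))
  if (mu[2L] - mu[1L] < 1e-12) return(mu[1L])
  glo <- g(mu[1L]); ghi <- g(mu[2L])
  if (glo >= 0) return(mu[1L])        # high component dominates throughout
  if (ghi <= 0) return(mu[2L])
  uniroot(g, c(mu[1L], mu[2L]), tol = 1e-12)$root
}

#' Assign binary abundance labels from a fitted mixture
#'
#' Labels each value by the mixture component with the higher posterior
#' probability, with 1 mapped to the higher-mean component. The decision is
#' realized as a single cutoff located at the posterior boundary between
#' the two component means, which guarantees monotone labels (x <= y
#' implies label(x) <= label(y)) even when unequal variances make the raw
#' posterior rule non-monotone. The maximum of `values` is always labeled
#' 1.
#'
#' @param params a `gmm2` fit from [fitGMM2()].
#' @param values numeric vector to label.
#' @return integer vector of 0/1 labels.
#' @export
assignLabels <- function(params, values) {
  cut <- .gmm2Cutoff(params)
  lab <- as.integer(values > cut)
  if (!any(lab == 1L)) lab[values == max(values)] <- 1L
  lab
}

#' Discretize a fraction table into binary abundance states
#'
#' Applies an independent two-component mixture fit to every cell type
#' column ("gmm" strategy) or a fixed split at the column midpoint
#' `(min + max) / 2` ("midpoint"). Columns that are degenerate under the
#' mixture (constant values, vanishing component) automatically fall back
#' to the midpoint rule; the per-column strategy actually used is recorded
#' in the result.
#'
#' Under the default `"log"` transform the mixture is fitted to log
#' fractions rather than raw ones. Composition fractions carry
#' multiplicative noise (every value shares the sample's renormalizing
#' denominator), so on the raw scale the high-abundance cluster is much
#' wider than the low one and the likelihood can prefer splitting the wide
#' cluster instead of the gap between the regimes; the log scale
#' symmetrizes the two clusters. The decision is still a single cutoff on
#' the fraction scale (the back-transformed log cutoff), so labels remain
#' monotone in the fraction. Zero fractions are floored at half the
#' smallest positive value before taking logs.
#'
#' @param ft a [FractionTable-class].
#' @param strategy `"gmm"` (default) or `"midpoint"`.
#' @param transform scale on which the mixture is fitted: `"log"`
#'   (default) or `"identity"`. The midpoint strategy always works on raw
#'   fractions.
#' @param maxSdRatio passed to [fitGMM2()]; 3 by default here: the two
#'   abundance regimes have comparable (within ~3x) spread on the log
#'   scale, and bounding the variance ratio keeps the small-sample fit
#'   from splitting a tight sub-cluster of one regime instead of the gap
#'   between regimes.
#' @param seed integer seed; column fits use seeds derived from it, so the
#'   result is reproducible.
#' @return a [BinaryMatrix-class].
#' @examples
#' ft <- newFractionTable(
#'   matrix(c(0.1, 0.1, 0.5, 0.5, 0.2, 0.3, 0.2, 0.3), 4, 2,
#'          dimnames = list(paste0("s", 1:4), c("A", "B"))),
#'   rep("ctrl", 4))
#' states(discretizeFractions(ft, seed = 1))
#' @export
discretizeFractions <- function(ft, strategy = c("gmm", "midpoint"),
                                transform = c("log", "identity"),
                                seed = 1L, maxSdRatio = 3) {
  strategy <- match.arg(strategy)
  transform <- match.arg(transform)
  v <- ft@values
  out <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  used <- setNames(rep(strategy, ncol(v)), colnames(v))
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    fitCol <- if (strategy == "gmm" && transform == "log")
      .logFloor(col) else col
    if (strategy == "gmm") {
      fit <- tryCatch(fitGMM2(fitCol, seed = .deriveSeed(seed, j),
                              maxSdRatio = maxSdRatio),
                      error = function(e) NULL)
      if (is.null(fit)) {
        used[j] <- "midpoint"
        out[, j] <- .midpointSplit(col)
        message("cell type '", colnames(v)[j],
                "' is degenerate under the mixture fit; midpoint fallback")
      } else {
        out[, j] <- assignLabels(fit, fitCol)
      }
    } else {
      out[, j] <- .midpointSplit(col)
    }
  }
  new("BinaryMatrix", states = out, conditions = ft@conditions,
      strategy = used)
}

.logFloor <- function(x) {
  pos <- x[x > 0]
  if (!length(pos)) return(x)          # all-zero: degenerate either way
  log(pmax(x, min(pos) / 2))
}

.midpointSplit <- function(col) as.integer(col > (min(col) + max(col)) / 2)

#' Leave-one-out stability of the discretization
#'
#' For each cell type, refits the mixture with each sample held out, labels
#' the held-out sample with the reduced fit, and reports the fraction of
#' samples whose held-out label agrees with the all-sample labeling. High
#' agreement means the binarization is not driven by any single sample.
#'
#' @param ft a [FractionTable-class] with at least 3 samples.
#' @param seed integer seed.
#' @return named numeric vector, per-cell-type agreement in \[0, 1\].
#' @export
looStability <- function(ft, seed = 1L) {
  v <- ft@values
  if (nrow(v) < 3L) stop("need at least 3 samples for leave-one-out")
  full <- states(discretizeFractions(ft, "gmm", seed = seed))
  agree <- setNames(numeric(ncol(v)), colnames(v))
  for (j in seq_len(ncol(v))) {
    lcol <- .logFloor(v[, j])
    ok <- logical(nrow(v))
    for (i in seq_len(nrow(v))) {
      lab <- tryCatch({
        fit <- fitGMM2(lcol[-i], seed = .deriveSeed(seed, j),
                       maxSdRatio = 3)
        as.integer(lcol[i] > .gmm2Cutoff(fit))
      }, error = function(e) .midpointHeldOut(v[-i, j], v[i, j]))
      ok[i] <- lab == full[i, j]
    }
    agree[j] <- mean(ok)
  }
  agree
}

.midpointHeldOut <- function(train, x)
  as.integer(x > (min(train) + max(train)) / 2)

# Seed handling that restores the caller's RNG state.
.safeSetSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
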