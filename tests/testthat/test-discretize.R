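test_that("EM recovers the parameters of a well-separated mixture", {
  set.seed(42)
  g1 <- rnorm(25, 0.1, 0.01)
  g2 <- rnorm(25, 0.5, 0.01)
  fit <- fitGMM2(c(g1, g2), seed = 7)
  # oracle: the known group means
  expect_lt(abs(fit$means[1] - mean(g1)), 0.02)
  expect_lt(abs(fit$means[2] - mean(g2)), 0.02)
  expect_true(fit$converged)
  # cross-check the reached likelihood against an independent EM
  mc <- mclust::mclustBIC(c(g1, g2), G = 2, modelNames = "V",
                          verbose = FALSE)
  # mclustBIC reports BIC = 2 loglik - k log n with k = 5 parameters
  mcLoglik <- (mc[1, "V"] + 5 * log(50)) / 2
  expect_gt(fit$loglik, mcLoglik - 0.1)
})

test_that("EM is translation-equivariant and rejects degenerate input", {
  set.seed(3)
  x <- c(rnorm(15, 0.2, 0.02), rnorm(15, 0.6, 0.02))
  f1 <- fitGMM2(x, seed = 5)
  f2 <- fitGMM2(x + 0.37, seed = 5)
  expect_equal(f2$means, f1$means + 0.37, tolerance = 1e-6)
  expect_identical(assignLabels(f2, x + 0.37), assignLabels(f1, x))
  expect_error(fitGMM2(rep(0.3, 10)), "degenerate")
})

test_that("EM log-likelihood trace is non-decreasing (property sweep)", {
  set.seed(11)
  for (i in 1:25) {
    x <- c(rnorm(10 + i %% 7, runif(1), runif(1, 0.01, 0.1)),
           rnorm(8 + i %% 5, runif(1, 0.5, 1), runif(1, 0.01, 0.1)))
    fit <- fitGMM2(x, seed = i, maxSdRatio = if (i %% 2) Inf else 3)
    expect_true(all(diff(fit$trace) > -1e-8))
  }
})

test_that("label assignment uses a single monotone cutoff", {
  p <- structure(list(weights = c(.5, .5), means = c(0.1, 0.5),
                      sds = c(.05, .05)), class = "gmm2")
  expect_identical(assignLabels(p, 0.45), 1L)
  # symmetric mixture: cutoff exactly at the midpoint
  expect_equal(InterCellBN:::.gmm2Cutoff(p), 0.3, tolerance = 1e-9)

  # unequal sds: raw posterior argmax is non-monotone in the tails; the
  # assigned labels must still be monotone and agree with the posterior
  # rule between the means (grid oracle)
  q <- structure(list(weights = c(.7, .3), means = c(0, 1),
                      sds = c(.6, .1)), class = "gmm2")
  grid <- seq(-2, 3, length.out = 501)
  lab <- assignLabels(q, grid)
  expect_true(all(diff(lab) >= 0))
  post1 <- function(x)
    q$weights[2] * dnorm(x, q$means[2], q$sds[2]) /
      (q$weights[1] * dnorm(x, q$means[1], q$sds[1]) +
         q$weights[2] * dnorm(x, q$means[2], q$sds[2]))
  cut <- InterCellBN:::.gmm2Cutoff(q)
  expect_gt(cut, q$means[1]); expect_lt(cut, q$means[2])
  expect_equal(post1(cut), 0.5, tolerance = 1e-6)
})

test_that("labels are invariant under increasing affine transforms", {
  set.seed(21)
  x <- c(rnorm(12, 0.2, 0.03), rnorm(18, 0.7, 0.05))
  base <- assignLabels(fitGMM2(x, seed = 2), x)
  for (ab in list(c(2, 0.1), c(0.5, -1), c(10, 3))) {
    y <- ab[1] * x + ab[2]
    expect_identical(assignLabels(fitGMM2(y, seed = 2), y), base)
  }
})

test_that("discretizeFractions matches oracles and falls back on degeneracy", {
  v <- cbind(A = c(0.1, 0.1, 0.5, 0.5), B = c(0.1, 0.1, 0.5, 0.5))
  rownames(v) <- paste0("s", 1:4)
  ft <- newFractionTable(v, rep("x", 4))
  bm <- discretizeFractions(ft, "gmm", seed = 1)
  expect_equal(unname(states(bm)[, "A"]), c(0L, 0L, 1L, 1L))
  # identical columns get identical labels
  expect_identical(states(bm)[, "A"], states(bm)[, "B"])

  v2 <- cbind(A = c(0, 1), B = c(0.3, 0.7))
  rownames(v2) <- c("s1", "s2")
  bm2 <- discretizeFractions(newFractionTable(v2, c("x", "x")),
                             "midpoint")
  expect_equal(unname(states(bm2)[, "A"]), c(0L, 1L))

  # constant column: gmm degenerates, midpoint fallback is recorded
  v3 <- cbind(A = c(0.2, 0.2, 0.2, 0.2), B = c(0.1, 0.1, 0.6, 0.6))
  rownames(v3) <- paste0("s", 1:4)
  expect_message(
    bm3 <- discretizeFractions(newFractionTable(v3, rep("x", 4)), "gmm",
                               seed = 1),
    "midpoint fallback")
  expect_identical(unname(bm3@strategy), c("midpoint", "gmm"))
})

test_that("discretization is reproducible and respects label polarity", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    v <- matrix(runif(2 * n, 0.01, 0.4), n, 2,
                dimnames = list(paste0("s", 1:n), c("A", "B")))
    ft <- newFractionTable(v, rep("x", n))
    b1 <- suppressMessages(discretizeFractions(ft, seed = 123))
    b2 <- suppressMessages(discretizeFractions(ft, seed = 123))
    expect_identical(states(b1), states(b2))
    # the sample with the largest fraction is never labeled 0
    for (j in 1:2)
      expect_identical(states(b1)[which.max(v[, j]), j], 1L)
  }
})

test_that("leave-one-out labeling is stable for separated clusters", {
  set.seed(5)
  lowhigh <- rep(c(0, 1), each = 10)
  v <- cbind(A = 0.1 + 0.3 * lowhigh + rnorm(20, 0, 0.02),
             B = 0.05 + 0.35 * lowhigh + rnorm(20, 0, 0.02))
  rownames(v) <- paste0("s", 1:20)
  agree <- looStability(newFractionTable(v, rep("x", 20)), seed = 1)
  expect_true(all(agree >= 0.9))

  # perfectly bimodal, zero overlap: perfect agreement
  v2 <- cbind(A = rep(c(0.1, 0.5), each = 5))
  rownames(v2) <- paste0("s", 1:10)
  expect_equal(unname(looStability(newFractionTable(v2, rep("x", 10)),
                                   seed = 1)), 1)

  expect_error(looStability(newFractionTable(
    matrix(c(0.1, 0.5), 2, 1, dimnames = list(c("s1", "s2"), "A")),
    c("x", "x"))), "at least 3")
})
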