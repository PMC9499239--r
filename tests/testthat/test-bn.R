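# Independent scoring oracle: explicit loops over parent configurations.
oracleLoglik <- function(D, dag) {
  total <- 0
  for (q in dag@nodes) {
    pa <- dag@edges[dag@edges[, 2] == q, 1]
    if (length(pa) == 0) {
      configs <- matrix(0L, nrow(D), 0)
    } else {
      configs <- D[, pa, drop = FALSE]
    }
    key <- apply(configs, 1, paste, collapse = ",")
    for (k in unique(key)) {
      rows <- key == k
      n1 <- sum(D[rows, q] == 1); n0 <- sum(rows) - n1
      tot <- n0 + n1
      if (n0 > 0) total <- total + n0 * log(n0 / tot)
      if (n1 > 0) total <- total + n1 * log(n1 / tot)
    }
  }
  total
}

test_that("network log-likelihood matches closed forms and the counting oracle", {
  D <- cbind(A = c(1L, 1L, 1L, 0L))
  expect_equal(bnLoglik(D, newDag("A")), 3 * log(0.75) + log(0.25))

  # deterministic copy: the child's local term is exactly 0
  D2 <- cbind(A = c(0L, 0L, 1L, 1L), B = c(0L, 0L, 1L, 1L))
  dag2 <- newDag(c("A", "B"), rbind(c("A", "B")))
  expect_equal(bnLoglik(D2, dag2), bnLoglik(D2[, "A", drop = FALSE],
                                            newDag("A")))

  set.seed(1)
  for (i in 1:10) {
    D3 <- matrix(rbinom(32, 1, 0.5), 8, 4,
                 dimnames = list(NULL, c("A", "B", "C", "E")))
    dag3 <- newDag(c("A", "B", "C", "E"),
                   rbind(c("A", "B"), c("A", "C"), c("B", "E"),
                         c("C", "E")))
    expect_equal(bnLoglik(D3, dag3), oracleLoglik(D3, dag3),
                 tolerance = 1e-10)
  }
  expect_error(bnLoglik(D2, newDag(c("A", "Z"))), "Z")
})

test_that("BIC penalty follows Dim(G) = sum of 2^parents", {
  set.seed(2)
  D <- matrix(rbinom(40, 1, 0.5), 10, 4,
              dimnames = list(NULL, c("A", "B", "C", "E")))
  empty <- newDag(colnames(D))
  expect_equal(bicScore(D, empty),
               bnLoglik(D, empty) - 0.5 * 4 * log(10))
  one <- newDag(colnames(D), rbind(c("A", "B")))
  # adding one parent to a parentless binary node costs 0.5 log N extra
  expect_equal((bnLoglik(D, one) - bicScore(D, one)) -
                 (bnLoglik(D, empty) - bicScore(D, empty)),
               0.5 * log(10))
})

test_that("all 25 three-node DAGs are enumerated and scored consistently", {
  dags <- allThreeNodeDags()
  expect_length(dags, 25L)
  set.seed(3)
  D <- matrix(rbinom(36, 1, 0.5), 12, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  for (dag in dags)
    expect_equal(bicScore(D, dag),
                 oracleLoglik(D, dag) -
                   0.5 * sum(2^table(factor(dag@edges[, 2],
                                            levels = dag@nodes))) * log(12))
})

test_that("Hiton-PC screening finds chains and ignores independence", {
  set.seed(4)
  # independent columns: skeleton essentially empty at large N
  nEdges <- replicate(10, {
    D <- matrix(rbinom(1500, 1, 0.5), 500, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    sum(hitonPC(D, alpha = 0.05)) / 2
  })
  expect_lt(mean(nEdges), 0.5)

  # chain A -> B -> C with strong dependence: A-B and B-C, not A-C
  set.seed(5)
  a <- rbinom(500, 1, 0.5)
  b <- ifelse(runif(500) < 0.9, a, 1 - a)
  cc <- ifelse(runif(500) < 0.9, b, 1 - b)
  D <- cbind(A = a, B = b, C = cc)
  skel <- hitonPC(D, alpha = 0.05, maxCondSize = 3)
  expect_true(skel["A", "B"] && skel["B", "C"])
  expect_false(skel["A", "C"])

  # two samples: every test is underpowered, empty skeleton, no crash
  D2 <- cbind(A = c(0L, 1L), B = c(1L, 0L), C = c(0L, 1L))
  expect_false(any(hitonPC(D2)))

  # constant column warns and gets no neighbours
  D3 <- cbind(A = rep(1L, 20), B = rbinom(20, 1, 0.5))
  expect_warning(s3 <- hitonPC(D3), "constant")
  expect_false(any(s3["A", ]))
})

test_that("hill climbing reaches the exhaustive optimum on 3 nodes", {
  dags <- allThreeNodeDags()
  set.seed(6)
  for (rep in 1:20) {
    # strong-signal data: B copies A, C copies B, some noise
    n <- sample(8:16, 1)
    a <- rbinom(n, 1, 0.5)
    b <- ifelse(runif(n) < 0.85, a, 1 - a)
    cc <- ifelse(runif(n) < 0.85, b, 1 - b)
    D <- cbind(A = a, B = b, C = cc)
    if (length(unique(a)) < 2) next
    best <- max(vapply(dags, function(g) bicScore(D, g), numeric(1)))
    got <- bicScore(D, hillClimb(D, debug = TRUE))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("hill climbing on noise returns the empty graph and respects the skeleton", {
  set.seed(7)
  D <- matrix(rbinom(600, 1, 0.5), 200, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  expect_identical(nrow(edges(hillClimb(D))), 0L)

  # perfect copy with skeleton {A-B}: exactly one edge between A and B
  a <- rbinom(20, 1, 0.5)
  D2 <- cbind(A = a, B = a, C = rbinom(20, 1, 0.5))
  skel <- matrix(FALSE, 3, 3, dimnames = list(colnames(D2), colnames(D2)))
  skel["A", "B"] <- skel["B", "A"] <- TRUE
  e <- edges(hillClimb(D2, skeleton = skel))
  expect_identical(nrow(e), 1L)
  expect_setequal(as.character(e), c("A", "B"))
})

test_that("learned graphs are always acyclic DAGs without self loops", {
  set.seed(8)
  for (i in 1:30) {
    n <- sample(c(10, 20, 40), 1)
    p <- sample(3:6, 1)
    D <- matrix(rbinom(n * p, 1, runif(1, 0.3, 0.7)), n, p,
                dimnames = list(NULL, LETTERS[1:p]))
    dag <- suppressWarnings(learnNetwork(D, alpha = 0.05))
    expect_s4_class(dag, "Dag")   # validity enforces acyclicity
    if (nrow(edges(dag)))
      expect_false(any(edges(dag)[, 1] == edges(dag)[, 2]))
  }
})

test_that("CPT estimation matches closed forms and normalizes", {
  D <- cbind(A = c(1L, 1L, 1L, 0L))
  m <- fitCPTs(D, newDag("A"), pseudocount = 0)
  expect_equal(unname(m@cpts$A[1, "1"]), 0.75)

  # unseen parent configuration with Laplace smoothing: probability 1/2
  D2 <- cbind(A = c(0L, 0L, 0L, 0L), B = c(0L, 1L, 0L, 1L))
  m2 <- fitCPTs(D2, newDag(c("A", "B"), rbind(c("A", "B"))),
                pseudocount = 1)
  expect_equal(unname(m2@cpts$B["1", "1"]), 0.5)

  set.seed(9)
  D3 <- matrix(rbinom(60, 1, 0.4), 15, 4,
               dimnames = list(NULL, c("A", "B", "C", "E")))
  m3 <- fitCPTs(D3, newDag(colnames(D3),
                           rbind(c("A", "C"), c("B", "C"), c("C", "E"))))
  for (cpt in m3@cpts)
    expect_equal(unname(rowSums(cpt)), rep(1, nrow(cpt)))
})

test_that("DAG export writes edge lists and DOT", {
  dag <- newDag(c("A", "B"), rbind(c("A", "B")))
  f <- tempfile(fileext = ".tsv")
  writeDag(dag, f)
  expect_equal(read.delim(f, comment.char = "#")$from, "A")
  f2 <- tempfile(fileext = ".dot")
  writeDag(dag, f2, format = "dot")
  expect_true(any(grepl("\"A\" -> \"B\"", readLines(f2))))
})
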