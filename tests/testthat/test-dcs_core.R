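test_that("network assembly places the incidence blocks and unit diagonal", {
  kam1 <- matrix(1, 1, 1, dimnames = list("d1", "l1"))
  kam2 <- matrix(1, 1, 1, dimnames = list("m1", "l1"))
  net <- buildNetwork(kam1, kam2, b = 6)
  am <- networkAdjacency(net)
  want <- matrix(c(1, 1, 0,
                   1, 1, 1,
                   0, 1, 1), 3, byrow = TRUE,
                 dimnames = list(c("d1", "l1", "m1"), c("d1", "l1", "m1")))
  expect_equal(am, want)

  # all-zero incidences give the identity
  z1 <- matrix(0, 2, 2, dimnames = list(c("d1", "d2"), c("l1", "l2")))
  z2 <- matrix(0, 2, 2, dimnames = list(c("m1", "m2"), c("l1", "l2")))
  expect_equal(networkAdjacency(buildNetwork(z1, z2)),
               diag(6), ignore_attr = TRUE)

  withr::local_seed(5)
  k1 <- matrix(rbinom(12, 1, 0.5), 3, 4,
               dimnames = list(paste0("d", 1:3), paste0("l", 1:4)))
  k2 <- matrix(rbinom(8, 1, 0.5), 2, 4,
               dimnames = list(paste0("m", 1:2), paste0("l", 1:4)))
  am2 <- networkAdjacency(buildNetwork(k1, k2))
  expect_equal(am2, t(am2))

  colnames(k2) <- paste0("L", 1:4)
  expect_error(buildNetwork(k1, k2), "lncRNA label mismatch")
})

test_that("bounded shortest paths match the BFS oracle on random graphs", {
  withr::local_seed(99)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    am <- randomAdjacency(n, pEdge = runif(1, 0.05, 0.3))
    for (b in 1:6) {
      expect_identical(shortestPaths(am, b = b), bfsSpmOracle(am, b))
    }
  }
})

test_that("per-node BFS route agrees with the matrix-power route", {
  withr::local_seed(4)
  for (rep in 1:10) {
    am <- randomAdjacency(sample(5:25, 1), pEdge = 0.15)
    for (b in c(1, 3, 6)) {
      expect_identical(dcsMir:::.spmBfs(am, b), shortestPaths(am, b = b))
    }
  }
})

test_that("SPM structure: unit diagonal, symmetry, adjacency at 1,
           unreachable sentinel, b-monotone reachability", {
  # two disconnected components
  am <- matrix(0, 4, 4, dimnames = list(paste0("v", 1:4), paste0("v", 1:4)))
  am[1, 2] <- am[2, 1] <- 1
  am[3, 4] <- am[4, 3] <- 1
  diag(am) <- 1
  spm <- shortestPaths(am, b = 6)
  expect_equal(unname(diag(spm)), rep(1L, 4))
  expect_identical(spm, t(spm))
  expect_identical(spm == 1L, am == 1)
  expect_equal(spm[1, 3], 0L)  # cross-component sentinel

  withr::local_seed(13)
  amr <- randomAdjacency(15, 0.1)
  prev <- shortestPaths(amr, b = 1)
  for (b in 2:6) {
    cur <- shortestPaths(amr, b = b)
    expect_true(all(cur[prev > 0] > 0))  # reachable set non-decreasing in b
    prev <- cur
  }
})

test_that("distance correlation sets contain the node and respect symmetry", {
  # path a-b-c-d with b=2 reaches two steps
  am <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  am[cbind(1:3, 2:4)] <- 1
  am <- am + t(am); diag(am) <- 1
  spm <- shortestPaths(am, b = 2)
  expect_setequal(distanceCorrelationSet(spm, "a", b = 2), c("a", "b", "c"))

  # isolated node is its own set
  iso <- diag(3); dimnames(iso) <- list(paste0("v", 1:3), paste0("v", 1:3))
  expect_equal(distanceCorrelationSet(shortestPaths(iso, b = 6), "v1", 6),
               "v1")

  # star with three leaves at b=1 reaches every leaf
  star <- matrix(0, 4, 4, dimnames = list(c("c", "x", "y", "z"),
                                          c("c", "x", "y", "z")))
  star[1, 2:4] <- star[2:4, 1] <- 1; diag(star) <- 1
  expect_setequal(distanceCorrelationSet(shortestPaths(star, b = 1), "c", 1),
                  c("c", "x", "y", "z"))

  # membership is mutual because SPM is symmetric
  withr::local_seed(21)
  amr <- randomAdjacency(12, 0.2)
  spmr <- shortestPaths(amr, b = 3)
  for (i in rownames(amr)) {
    for (j in distanceCorrelationSet(spmr, i, 3)) {
      expect_true(i %in% distanceCorrelationSet(spmr, j, 3))
    }
  }
})

test_that("distance coefficients follow SPM^(b+1) with zero sentinel", {
  spm <- matrix(c(1L, 2L, 0L,
                  2L, 1L, 1L,
                  0L, 1L, 1L), 3, byrow = TRUE)
  p <- distanceCoefficients(spm, b = 6)
  expect_equal(p[1, 1], 1)       # SPM 1 -> 1 for any b
  expect_equal(p[1, 2], 2^7)     # 128
  expect_equal(p[1, 3], 0)       # unreachable
  pInv <- distanceCoefficients(spm, b = 6, weight = "inverse")
  expect_equal(pInv[1, 2], 2^-7)
  expect_equal(pInv[1, 3], 0)
})

test_that("distance correlation matrix applies the block-wise weighting", {
  lab <- function(x) list(x, x)
  fdd <- similarityMatrix(matrix(1, 1, 1, dimnames = lab("d1")), "FDD")
  fll <- similarityMatrix(matrix(1, 1, 1, dimnames = lab("l1")), "FLL")
  fmm <- similarityMatrix(matrix(1, 1, 1, dimnames = lab("m1")), "FMM")
  spm <- matrix(c(1L, 1L, 2L,
                  1L, 1L, 1L,
                  2L, 1L, 1L), 3, byrow = TRUE)
  p <- distanceCoefficients(spm, b = 6)
  dcm <- distanceCorrelationMatrix(p, spm, fdd, fll, fmm, b = 6)
  expect_equal(dcm[1, 1], exp(1))          # disease diagonal: P=1 times e^FDD
  expect_equal(dcm[1, 3], 128 * (2 / 6))   # cross-type: P times SPM/b
  expect_equal(dcm[1, 2], 1 * (1 / 6))     # disease-lncRNA cross block

  # multiplicative zero where P is zero
  spm0 <- spm; spm0[1, 3] <- 0L; spm0[3, 1] <- 0L
  p0 <- distanceCoefficients(spm0, b = 6)
  dcm0 <- distanceCorrelationMatrix(p0, spm0, fdd, fll, fmm, b = 6)
  expect_equal(dcm0[1, 3], 0)

  expect_error(distanceCorrelationMatrix(p[1:2, 1:2], spm, fdd, fll, fmm, 6),
               "dimension mismatch")
})

test_that("association-degree matrix is the normalized row+column sums", {
  dcm <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  pm <- outer(rowSums(dcm), colSums(dcm), "+") / 2
  expect_equal(pm[1, 2], 4.5)  # hand check: ((1+2) + (2+4)) / 2

  # constant DCM of value c gives constant PM of 2c
  dcmC <- matrix(0.7, 4, 4)
  pmRes <- predictionMatrix(dcmC, D = 1, L = 2, M = 1)
  expect_true(all(abs(pmRes$pm - 1.4) < 1e-12))
  expect_equal(dim(pmRes$c13), c(1L, 1L))

  z <- predictionMatrix(matrix(0, 3, 3), 1, 1, 1)
  expect_true(all(z$pm == 0))

  # c13 is exactly the disease-rows by miRNA-columns block
  withr::local_seed(2)
  dcmR <- matrix(runif(36), 6, 6,
                 dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  res <- predictionMatrix(dcmR, D = 2, L = 3, M = 1)
  expect_equal(res$c13, res$pm[1:2, 6, drop = FALSE])
})

test_that("final scores smooth C13 by the two similarities", {
  lab <- function(x) list(x, x)
  idD <- similarityMatrix(matrix(diag(2), 2, dimnames = lab(c("d1", "d2"))),
                          "FDD")
  idM <- similarityMatrix(matrix(diag(2), 2, dimnames = lab(c("m1", "m2"))),
                          "FMM")
  c13 <- matrix(c(0.1, 0.9, 0.4, 0.2), 2,
                dimnames = list(c("d1", "d2"), c("m1", "m2")))
  res <- finalScores(idD, c13, idM)
  expect_equal(scores(res), c13)  # identity smoothing

  one <- function(x, v, kind) similarityMatrix(
    matrix(v, 1, 1, dimnames = lab(x)), kind)
  scalar <- finalScores(one("d", 2, "FDD"),
                        matrix(3, 1, 1, dimnames = list("d", "m")),
                        one("m", 4, "FMM"))
  expect_equal(as.numeric(scores(scalar)), 24)

  zero <- finalScores(idD, matrix(0, 2, 2,
                                  dimnames = list(c("d1", "d2"),
                                                  c("m1", "m2"))), idM)
  expect_true(all(scores(zero) == 0))
  expect_error(finalScores(idD, matrix(0, 3, 2), idM), "dimension mismatch")
})

test_that("ranking accessors order by score with label tie-breaks", {
  fdd <- similarityMatrix(matrix(diag(2), 2,
                                 dimnames = list(c("d1", "d2"),
                                                 c("d1", "d2"))), "FDD")
  fmm <- similarityMatrix(matrix(diag(3), 3,
                                 dimnames = list(paste0("m", 1:3),
                                                 paste0("m", 1:3))), "FMM")
  c13 <- matrix(c(0.5, 0.1,
                  0.9, 0.1,
                  0.5, 0.8), 2,
                dimnames = list(c("d1", "d2"), paste0("m", 1:3)))
  res <- finalScores(fdd, c13, fmm)
  top <- rankedPairs(res, disease = "d1")
  expect_equal(top$mirna, c("m2", "m1", "m3"))  # tie 0.5 broken by label
  expect_equal(top$diseaseRank, 1:3)
  all <- rankedPairs(res)
  expect_equal(all$globalRank, seq_len(6))
  expect_equal(all$score, sort(all$score, decreasing = TRUE))
})

test_that("the pipeline is deterministic end to end", {
  d <- generateTripartite(syntheticConfig(nDiseases = 10, nLncrnas = 12,
                                          nMirnas = 10, nBlocks = 2,
                                          seed = 8))
  run <- function() {
    pred <- predictAssociations(d$lncDisease, d$lncMirna,
                                ontology = d$ontology, b = 4)
    path <- tempfile(fileext = ".tsv")
    utils::write.table(rankedPairs(pred), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    path
  }
  p1 <- run(); p2 <- run()
  expect_identical(readLines(p1), readLines(p2))
  file.remove(p1, p2)
})
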