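test_that("GIP kernel matches hand-derived values", {
  # orthogonal unit profiles: sum of squared norms 2, bandwidth 1,
  # squared distance 2 -> off-diagonal exp(-2)
  p <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  k <- simValues(gipKernel(p))
  expect_equal(k["a", "b"], exp(-2))
  expect_equal(diag(k), c(a = 1, b = 1))

  # identical profiles: all ones
  same <- gipKernel(matrix(1, 2, 2, dimnames = list(c("a", "b"), NULL)))
  expect_true(all(simValues(same) == 1))

  expect_error(gipKernel(matrix(0, 2, 2)), "all-zero")
})

test_that("GIP kernel is symmetric, PSD and column-permutation invariant", {
  withr::local_seed(7)
  for (rep in 1:10) {
    p <- matrix(rbinom(6 * 9, 1, 0.4), nrow = 6,
                dimnames = list(paste0("e", 1:6), NULL))
    if (sum(p) == 0) p[1, 1] <- 1
    k <- simValues(gipKernel(p))
    expect_equal(k, t(k))
    expect_true(all(k >= 0 & k <= 1))
    expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    perm <- sample(ncol(p))
    expect_equal(simValues(gipKernel(p[, perm])), k)
  }
})

test_that("logistic transform matches its closed form", {
  d <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- simValues(logisticTransform(similarityMatrix(d, "DGS")))
  expect_equal(f["a", "b"], 1e-4)
  expect_equal(f["a", "a"], 1 / (1 + 9999 * exp(-15)))
  mid <- matrix(log(9999) / 15, 1, 1, dimnames = list("x", "x"))
  expect_equal(simValues(logisticTransform(similarityMatrix(mid, "DGS")))[1, 1],
               0.5)
  expect_equal(simKind(logisticTransform(similarityMatrix(d, "DGS"))), "FDGS")
})

test_that("lncRNA edge weights are edge fractions", {
  inc <- matrix(c(1, 1, 0,
                  1, 0, 0,
                  1, 1, 0), 3, byrow = TRUE,
                dimnames = list(c("d1", "d2", "d3"), c("l1", "l2", "l3")))
  w <- lncrnaEdgeWeights(inc)
  expect_equal(unname(w), c(3 / 5, 2 / 5, 0))
  all4 <- matrix(1, 4, 1, dimnames = list(letters[1:4], "l"))
  expect_equal(unname(lncrnaEdgeWeights(all4)), 1)
  expect_error(lncrnaEdgeWeights(matrix(0, 2, 2)), "empty edge set")
})

test_that("functional similarity follows the shared/one-sided weighting", {
  # identical neighborhoods give 1
  inc <- matrix(c(1, 1, 1, 1), 2, byrow = TRUE,
                dimnames = list(c("d1", "d2"), c("l1", "l2")))
  expect_equal(simValues(functionalSimilarity(inc, "FSD"))["d1", "d2"], 1)

  # disjoint single neighbors, each lncRNA on 1 of 4 edges:
  # (C(l1) + C(l2)) / 2 = (0.25 + 0.25) / 2 = 0.25
  inc2 <- matrix(c(1, 0, 0, 0,
                   0, 1, 0, 0,
                   0, 0, 1, 1), 3, byrow = TRUE,
                 dimnames = list(c("d1", "d2", "d3"), paste0("l", 1:4)))
  expect_equal(simValues(functionalSimilarity(inc2, "FSD"))["d1", "d2"], 0.25)

  # empty neighborhood: zero off-diagonal, one on the diagonal
  inc3 <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE,
                 dimnames = list(c("d1", "d2"), c("l1", "l2")))
  v <- simValues(functionalSimilarity(inc3, "FSD"))
  expect_equal(v["d1", "d2"], 0)
  expect_equal(v["d2", "d2"], 1)
})

test_that("functional similarity is 1 for coinciding neighborhoods and,
           at fixed lncRNA weights, never rises when a shared neighbor
           is removed", {
  # enumerate all 3-lncRNA neighborhood pairs on a fixed weight scale
  # (weights belong to the whole bipartite graph, so they are held
  # constant while the pair's neighborhoods vary)
  w <- c(0.2, 0.5, 0.3)
  combos <- expand.grid(rep(list(0:1), 6))
  for (r in seq_len(nrow(combos))) {
    ni <- as.numeric(combos[r, 1:3]); nj <- as.numeric(combos[r, 4:6])
    inc <- rbind(i = ni, j = nj)
    colnames(inc) <- paste0("l", 1:3)
    s <- simValues(functionalSimilarity(inc, "FSD", weights = w))["i", "j"]
    if (any(ni & nj) && identical(ni, nj)) expect_equal(s, 1)
    if (!any(ni & nj) && any(ni | nj)) expect_lt(s, 1)  # weights all < 1
    shared <- which(ni & nj)
    if (length(shared)) {
      inc2 <- inc; inc2[, shared[1]] <- 0
      s2 <- simValues(functionalSimilarity(inc2, "FSD", weights = w))["i", "j"]
      expect_lte(s2, s + 1e-12)
    }
  }
})

test_that("integration averages matrices elementwise", {
  lab <- list(c("a", "b"), c("a", "b"))
  mk <- function(x, kind) similarityMatrix(
    matrix(c(1, x, x, 1), 2, dimnames = lab), kind)
  fdd <- integrateSimilarity(list(mk(0.3, "SSD"), mk(0.6, "FDGS"),
                                  mk(0.9, "FSD")), "FDD")
  expect_equal(simValues(fdd)["a", "b"], 0.6)
  same <- integrateSimilarity(list(mk(0.4, "SSD"), mk(0.4, "FDGS"),
                                   mk(0.4, "FSD")), "FDD")
  expect_equal(simValues(same)["a", "b"], 0.4)
  ones <- similarityMatrix(matrix(1, 2, 2, dimnames = lab), "MGS")
  zeros <- similarityMatrix(matrix(0, 2, 2, dimnames = lab), "FSM")
  expect_equal(simValues(integrateSimilarity(list(ones, zeros), "FMM"))[1, 2],
               0.5)
  bad <- similarityMatrix(matrix(1, 3, 3,
                                 dimnames = list(letters[1:3], letters[1:3])),
                          "FSM")
  expect_error(integrateSimilarity(list(ones, bad), "FMM"), "label mismatch")
})

test_that("the similarity bundle is symmetric, finite and in range", {
  withr::local_seed(11)
  d <- generateTripartite(syntheticConfig(nDiseases = 8, nLncrnas = 10,
                                          nMirnas = 8, nBlocks = 2, seed = 3))
  shared <- restrictToSharedLncrnas(d$lncDisease, d$lncMirna)
  kam1 <- incidenceMatrix(shared$ld, colOrder = sourceNames(shared$ld))
  kam2 <- incidenceMatrix(shared$lm, colOrder = sourceNames(shared$ld))
  sims <- buildSimilarities(kam1, kam2, dag = d$ontology)
  for (nm in names(sims)) {
    v <- simValues(sims[[nm]])
    expect_equal(v, t(v))
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= 1))
  }
  # kernels additionally have unit diagonal and are PSD
  for (nm in c("dgs", "mgs", "lgs1", "lgs2")) {
    v <- simValues(sims[[nm]])
    expect_equal(unname(diag(v)), rep(1, nrow(v)))
    expect_gte(min(eigen(v, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # logistic diagonal is the transform of 1, not 1
  expect_equal(unname(diag(simValues(sims$fdgs))),
               rep(1 / (1 + 9999 * exp(-15)), nrow(kam1)))
})

test_that("similarity matrices round-trip through labeled TSV", {
  m <- similarityMatrix(matrix(c(1, 0.25, 0.25, 1), 2,
                               dimnames = list(c("a b", "c"), c("a b", "c"))),
                        "FDD")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSimilarityMatrix(m, path)
  back <- readSimilarityMatrix(path, kind = "FDD")
  expect_equal(simValues(back), simValues(m))
})
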