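# ---------------------------------------------------------------------------
# Kernel and functional similarities over the two incidence matrices.
# ---------------------------------------------------------------------------

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix with identical row/column names.
#' @param kind similarity tag (see [SimilarityMatrix-class]).
#' @return a [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(values, kind) {
  new("SimilarityMatrix", values = values, kind = kind)
}

#' @rdname SimilarityMatrix-class
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

#' @rdname SimilarityMatrix-class
#' @export
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  cat(sprintf("SimilarityMatrix [%s]: %d x %d, range [%.4g, %.4g]\n",
              object@kind, nrow(v), ncol(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

.labelsOf <- function(x) rownames(simValues(x))

#' Gaussian interaction-profile kernel similarity
#'
#' Computes `exp(-gamma * ||x_i - x_j||^2)` between the rows of a binary
#' association-profile matrix, with one shared bandwidth
#' `gamma = n / sum_i ||x_i||^2` (n = number of profiles), i.e. the
#' inverse mean squared profile norm. Applied to the miRNA x lncRNA
#' incidence rows it yields the miRNA kernel, to the disease x lncRNA
#' rows the disease kernel, and to the transposed incidences the two
#' lncRNA kernels.
#'
#' @param profiles numeric matrix, one profile per row, with rownames.
#' @param kind tag for the resulting matrix (e.g. `"MGS"`, `"DGS"`,
#'   `"LGS1"`, `"LGS2"`).
#' @return a [SimilarityMatrix-class] with unit diagonal and entries in
#'   (0, 1].
#' @export
gipKernel <- function(profiles, kind = "GIP") {
  profiles <- as.matrix(profiles)
  total <- sum(profiles^2)
  if (total == 0) stop("all-zero profile matrix: kernel bandwidth undefined")
  gamma <- nrow(profiles) / total
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-gamma * d2)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  similarityMatrix(k, kind = kind)
}

#' Logistic transform of a kernel similarity
#'
#' Elementwise `1 / (1 + exp(-slope * x + offset))`. With the default
#' constants (slope 15, offset log(9999)) a similarity of 0 maps to
#' 1e-4 and the curve midpoint sits at `log(9999)/15 ~ 0.614`, which
#' sharpens the disease kernel before integration.
#'
#' @param x a [SimilarityMatrix-class] (entries in \[0, 1\]).
#' @param slope,offset logistic constants.
#' @return a [SimilarityMatrix-class] whose kind is the input kind
#'   prefixed with `"F"`; entries lie in (0, 1).
#' @export
logisticTransform <- function(x, slope = 15, offset = log(9999)) {
  stopifnot(is(x, "SimilarityMatrix"))
  v <- 1 / (1 + exp(-slope * simValues(x) + offset))
  similarityMatrix(v, kind = paste0("F", simKind(x)))
}

#' Per-lncRNA edge weights in a bipartite incidence
#'
#' The weight of a lncRNA is the fraction of all incidence edges it is
#' part of: `C(l) = deg(l) / |E|`. Used as the contribution of a lncRNA
#' that neighbors only one member of an entity pair in
#' [functionalSimilarity()].
#'
#' @param incidence binary matrix with lncRNAs on the columns.
#' @return named numeric vector over the columns, summing to 1.
#' @export
lncrnaEdgeWeights <- function(incidence) {
  incidence <- as.matrix(incidence)
  total <- sum(incidence)
  if (total == 0) stop("empty edge set: lncRNA weights undefined")
  colSums(incidence) / total
}

#' lncRNA-mediated functional similarity
#'
#' For entities i, j with lncRNA neighborhoods N(i), N(j):
#' every shared neighbor contributes 1, every one-sided neighbor
#' contributes its edge weight `C(l)` (see [lncrnaEdgeWeights()]), and
#' the sum is divided by the union size `|N(i) u N(j)|` (equivalently,
#' by inclusion-exclusion, `|N(i)| + |N(j)| - |N(i) n N(j)|`).
#' The diagonal is forced to 1; a pair with an empty neighborhood on
#' either side scores 0 (no lncRNA evidence, no similarity).
#'
#' @param incidence binary matrix, entities on the rows and lncRNAs on
#'   the columns (disease x lncRNA gives the disease functional
#'   similarity, miRNA x lncRNA the miRNA one).
#' @param kind tag for the result, `"FSD"` or `"FSM"`.
#' @param weights optional fixed per-lncRNA weight vector (one value per
#'   column); by default computed from `incidence` itself via
#'   [lncrnaEdgeWeights()]. Supplying weights from a larger graph lets a
#'   row subset be scored on the full graph's edge-weight scale.
#' @return a [SimilarityMatrix-class] with entries in \[0, 1\].
#' @export
functionalSimilarity <- function(incidence, kind = c("FSD", "FSM"),
                                 weights = NULL) {
  kind <- match.arg(kind)
  incidence <- as.matrix(incidence)
  n <- nrow(incidence)
  w <- if (!is.null(weights)) {
    stopifnot(length(weights) == ncol(incidence))
    weights
  } else if (sum(incidence) > 0) lncrnaEdgeWeights(incidence) else
    numeric(ncol(incidence))
  out <- diag(1, n)
  dimnames(out) <- list(rownames(incidence), rownames(incidence))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ni <- incidence[i, ] > 0
      for (j in seq(i + 1, n)) {
        nj <- incidence[j, ] > 0
        if (!any(ni) || !any(nj)) next  # empty neighborhood -> 0
        union <- ni | nj
        both <- ni & nj
        onesided <- union & !both
        out[i, j] <- out[j, i] <-
          (sum(both) + sum(w[onesided])) / sum(union)
      }
    }
  }
  similarityMatrix(out, kind = kind)
}

#' Integrate similarity matrices by unweighted averaging
#'
#' The disease integrated similarity averages the semantic, logistic
#' kernel and functional matrices; the miRNA one averages kernel and
#' functional; the lncRNA one averages the two kernels.
#'
#' @param parts list of [SimilarityMatrix-class] objects with identical
#'   shapes and label order.
#' @param kind tag for the result: `"FDD"`, `"FMM"` or `"FLL"`.
#' @return a [SimilarityMatrix-class].
#' @export
integrateSimilarity <- function(parts, kind = c("FDD", "FMM", "FLL")) {
  kind <- match.arg(kind)
  stopifnot(length(parts) >= 1)
  labs <- .labelsOf(parts[[1L]])
  for (p in parts) {
    stopifnot(is(p, "SimilarityMatrix"))
    if (!identical(.labelsOf(p), labs)) {
      stop("label mismatch between similarity matrices being integrated")
    }
  }
  acc <- Reduce(`+`, lapply(parts, simValues))
  similarityMatrix(acc / length(parts), kind = kind)
}

#' Compute the full similarity bundle for a pair of incidence matrices
#'
#' Convenience wrapper producing every similarity the predictor needs:
#' the disease semantic similarity (zeros off-diagonal when no ontology
#' is supplied), the four interaction-profile kernels, the logistic
#' transform of the disease kernel, the two functional similarities and
#' the three integrated matrices.
#'
#' @param kam1 disease x lncRNA binary incidence.
#' @param kam2 miRNA x lncRNA binary incidence (same lncRNA columns).
#' @param dag optional [OntologyDAG-class] covering the diseases.
#' @param slope,offset logistic constants, see [logisticTransform()].
#' @return a named list of [SimilarityMatrix-class] objects:
#'   `ssd`, `dgs`, `fdgs`, `mgs`, `lgs1`, `lgs2`, `fsd`, `fsm`,
#'   `fdd`, `fmm`, `fll`.
#' @export
buildSimilarities <- function(kam1, kam2, dag = NULL,
                              slope = 15, offset = log(9999)) {
  if (!identical(colnames(kam1), colnames(kam2))) {
    stop("kam1 and kam2 must share an identical ordered lncRNA axis")
  }
  diseases <- rownames(kam1)
  ssd <- if (is.null(dag)) {
    warning("no ontology supplied; semantic similarity is zero off-diagonal")
    m <- diag(1, nrow(kam1)); dimnames(m) <- list(diseases, diseases)
    similarityMatrix(m, kind = "SSD")
  } else {
    diseaseSemanticSimilarity(dag, diseases)
  }
  dgs <- gipKernel(kam1, kind = "DGS")
  fdgs <- logisticTransform(dgs, slope = slope, offset = offset)
  mgs <- gipKernel(kam2, kind = "MGS")
  lgs1 <- gipKernel(t(kam1), kind = "LGS1")
  lgs2 <- gipKernel(t(kam2), kind = "LGS2")
  fsd <- functionalSimilarity(kam1, kind = "FSD")
  fsm <- functionalSimilarity(kam2, kind = "FSM")
  list(
    ssd = ssd, dgs = dgs, fdgs = fdgs, mgs = mgs, lgs1 = lgs1, lgs2 = lgs2,
    fsd = fsd, fsm = fsm,
    fdd = integrateSimilarity(list(ssd, fdgs, fsd), kind = "FDD"),
    fmm = integrateSimilarity(list(mgs, fsm), kind = "FMM"),
    fll = integrateSimilarity(list(lgs1, lgs2), kind = "FLL")
  )
}

#' Write a similarity matrix as labeled TSV
#'
#' First row and first column carry the entity labels (full dense
#' square). [readSimilarityMatrix()] accepts the format back.
#'
#' @param x a [SimilarityMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(x, path) {
  stopifnot(is(x, "SimilarityMatrix"))
  utils::write.table(simValues(x), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @param kind tag to assign to the matrix read back.
#' @export
readSimilarityMatrix <- function(path, kind = "custom") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  # symmetrize away write/parse rounding
  m <- (m + t(m)) / 2
  similarityMatrix(m, kind = kind)
}
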