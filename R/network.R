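# ---------------------------------------------------------------------------
# Tripartite network, bounded shortest paths, distance-correlation scoring.
# ---------------------------------------------------------------------------

#' Assemble the tripartite disease-lncRNA-miRNA network
#'
#' Builds the block adjacency over the node order diseases, lncRNAs,
#' miRNAs: the disease-lncRNA block is the first incidence, the
#' lncRNA-miRNA block the transpose of the second, both mirrored for
#' symmetry; all other off-diagonal blocks are zero and the diagonal is
#' set to 1 (every node reaches itself at distance 1 by convention, so
#' the shortest-path recursion below is well defined).
#'
#' @param kam1 disease x lncRNA binary incidence matrix.
#' @param kam2 miRNA x lncRNA binary incidence matrix; must share the
#'   identical ordered lncRNA column labels with `kam1`.
#' @param b positive integer bandwidth (default 6).
#' @return a [TripartiteNetwork-class].
#' @export
buildNetwork <- function(kam1, kam2, b = 6L) {
  kam1 <- as.matrix(kam1); kam2 <- as.matrix(kam2)
  if (!identical(colnames(kam1), colnames(kam2))) {
    stop("lncRNA label mismatch between the two incidence matrices")
  }
  D <- nrow(kam1); L <- ncol(kam1); M <- nrow(kam2)
  N <- D + L + M
  am <- matrix(0, N, N)
  di <- seq_len(D); li <- D + seq_len(L); mi <- D + L + seq_len(M)
  am[di, li] <- kam1
  am[li, di] <- t(kam1)
  am[li, mi] <- t(kam2)
  am[mi, li] <- kam2
  diag(am) <- 1
  labels <- c(rownames(kam1), colnames(kam1), rownames(kam2))
  dimnames(am) <- list(labels, labels)
  new("TripartiteNetwork", adjacency = am,
      diseases = rownames(kam1), lncrnas = colnames(kam1),
      mirnas = rownames(kam2), b = as.integer(b))
}

#' @rdname buildNetwork
#' @param net a [TripartiteNetwork-class].
#' @export
networkAdjacency <- function(net) net@adjacency

setMethod("show", "TripartiteNetwork", function(object) {
  cat(sprintf(
    "TripartiteNetwork: %d diseases, %d lncRNAs, %d miRNAs, b = %d\n",
    length(object@diseases), length(object@lncrnas),
    length(object@mirnas), object@b))
})

#' Bounded shortest-path matrix
#'
#' `SPM(i, j)` is the length of the shortest path between i and j when
#' it does not exceed the bandwidth b, and 0 otherwise (the sentinel
#' for "unreachable within b"). Equivalently it is the smallest k with
#' a non-zero (i, j) entry of the k-th boolean power of the adjacency.
#' Computed by boolean matrix powers with early exit; for networks with
#' more than 5000 nodes a per-node breadth-first search is used instead.
#'
#' @param net a [TripartiteNetwork-class], or a symmetric binary
#'   adjacency matrix with unit diagonal.
#' @param b bandwidth; defaults to the network's own.
#' @return integer matrix with entries in `{0, 1, ..., b}`; the
#'   diagonal is 1 (unit diagonal of the adjacency).
#' @export
shortestPaths <- function(net, b = NULL) {
  if (is(net, "TripartiteNetwork")) {
    am <- net@adjacency
    if (is.null(b)) b <- net@b
  } else {
    am <- as.matrix(net)
    if (is.null(b)) stop("b must be given for a raw adjacency matrix")
  }
  b <- as.integer(b)
  stopifnot(b >= 1L)
  if (nrow(am) > 5000L) return(.spmBfs(am, b))
  spm <- matrix(0L, nrow(am), ncol(am), dimnames = dimnames(am))
  spm[am != 0] <- 1L
  reach <- am != 0
  k <- 1L
  while (k < b && !all(spm > 0L)) {
    k <- k + 1L
    reach <- (reach %*% am) > 0
    newly <- reach & spm == 0L
    if (!any(newly)) break  # connected component exhausted
    spm[newly] <- k
  }
  spm
}

# per-node truncated BFS; same contract as the matrix-power route
.spmBfs <- function(am, b) {
  n <- nrow(am)
  adj <- lapply(seq_len(n), function(i) which(am[i, ] != 0))
  spm <- matrix(0L, n, n, dimnames = dimnames(am))
  for (i in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[adj[[i]]] <- 1L
    frontier <- adj[[i]]
    k <- 1L
    while (k < b && length(frontier)) {
      k <- k + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- k
      frontier <- nxt
    }
    found <- !is.na(dist)
    spm[i, found] <- dist[found]
  }
  spm
}

#' Distance correlation set of a node
#'
#' All nodes within graph distance b of node i, including i itself
#' (its bounded shortest-path entry is 1 by the unit-diagonal
#' convention). Nodes unreachable within b (sentinel 0) are excluded.
#'
#' @param spm bounded shortest-path matrix from [shortestPaths()].
#' @param i node index or label.
#' @param b bandwidth used when `spm` was computed.
#' @return character vector of node labels (or integer indices when the
#'   matrix has no dimnames).
#' @export
distanceCorrelationSet <- function(spm, i, b) {
  row <- spm[i, ]
  hit <- which(row >= 1 & row <= b)
  if (!is.null(colnames(spm))) colnames(spm)[hit] else hit
}

#' Distance coefficients
#'
#' `P(i, j) = SPM(i, j)^(b+1)` for pairs within each other's distance
#' correlation set, 0 otherwise. The published exponent rewards distant
#' pairs; `weight = "inverse"` applies `SPM^-(b+1)` instead for the
#' near-rewarding alternative, with the published form as the default.
#'
#' @param spm bounded shortest-path matrix.
#' @param b bandwidth.
#' @param weight `"as_printed"` (default) or `"inverse"`.
#' @return numeric matrix; zero exactly where `spm` is zero.
#' @export
distanceCoefficients <- function(spm, b, weight = c("as_printed", "inverse")) {
  weight <- match.arg(weight)
  p <- matrix(0, nrow(spm), ncol(spm), dimnames = dimnames(spm))
  nz <- spm > 0
  expo <- if (weight == "as_printed") (b + 1) else -(b + 1)
  p[nz] <- as.numeric(spm[nz])^expo
  p
}

.blockIndex <- function(D, L, M) {
  list(d = seq_len(D), l = D + seq_len(L), m = D + L + seq_len(M))
}

#' Distance correlation matrix
#'
#' Weights the distance coefficients by similarity: within the disease,
#' lncRNA and miRNA diagonal blocks `DCM = P * exp(similarity)` using
#' the integrated disease/lncRNA/miRNA similarities; for every
#' cross-type pair `DCM = P * SPM / b`.
#'
#' @param p distance-coefficient matrix from [distanceCoefficients()].
#' @param spm bounded shortest-path matrix.
#' @param fdd,fll,fmm integrated [SimilarityMatrix-class] objects for
#'   diseases, lncRNAs and miRNAs (sizes D, L, M).
#' @param b bandwidth.
#' @return numeric (D+L+M) square matrix.
#' @export
distanceCorrelationMatrix <- function(p, spm, fdd, fll, fmm, b) {
  D <- nrow(simValues(fdd)); L <- nrow(simValues(fll))
  M <- nrow(simValues(fmm))
  N <- D + L + M
  if (!identical(dim(p), c(N, N)) || !identical(dim(spm), c(N, N))) {
    stop("dimension mismatch between P/SPM and the similarity blocks")
  }
  factor <- spm / b
  ix <- .blockIndex(D, L, M)
  factor[ix$d, ix$d] <- exp(simValues(fdd))
  factor[ix$l, ix$l] <- exp(simValues(fll))
  factor[ix$m, ix$m] <- exp(simValues(fmm))
  p * factor
}

#' Association-degree matrix and its disease x miRNA block
#'
#' `PM(i, j)` is the i-th row sum plus the j-th column sum of the
#' distance correlation matrix, divided by the node count. The block of
#' disease rows against miRNA columns is the raw prediction matrix.
#'
#' @param dcm distance correlation matrix.
#' @param D,L,M class sizes (diseases, lncRNAs, miRNAs).
#' @return list with elements `pm` (full matrix) and `c13`
#'   (disease x miRNA block).
#' @export
predictionMatrix <- function(dcm, D, L, M) {
  N <- D + L + M
  stopifnot(all(dim(dcm) == N))
  pm <- outer(rowSums(dcm), colSums(dcm), "+") / N
  dimnames(pm) <- dimnames(dcm)
  ix <- .blockIndex(D, L, M)
  list(pm = pm, c13 = pm[ix$d, ix$m, drop = FALSE])
}

#' Similarity-smoothed final scores
#'
#' `FAD = FDD %*% C13 %*% FMM`: the raw disease x miRNA block smoothed
#' on both sides by the integrated disease and miRNA similarities.
#'
#' @param fdd D x D integrated disease [SimilarityMatrix-class].
#' @param c13 D x M raw prediction block.
#' @param fmm M x M integrated miRNA [SimilarityMatrix-class].
#' @param params optional list of pipeline parameters carried along.
#' @return a [PredictionResult-class].
#' @export
finalScores <- function(fdd, c13, fmm, params = list()) {
  fddV <- simValues(fdd); fmmV <- simValues(fmm)
  if (nrow(fddV) != nrow(c13) || ncol(c13) != nrow(fmmV)) {
    stop("dimension mismatch: need D x D, D x M, M x M")
  }
  fad <- fddV %*% c13 %*% fmmV
  dimnames(fad) <- dimnames(c13)
  new("PredictionResult", fad = fad, c13 = c13,
      diseases = rownames(c13), mirnas = colnames(c13), params = params)
}

#' @rdname PredictionResult-class
#' @export
setMethod("scores", "PredictionResult", function(x) x@fad)

#' @rdname PredictionResult-class
#' @param disease optional disease label to restrict the ranking to.
#' @param n number of top pairs to return (default all).
#' @export
setMethod("rankedPairs", "PredictionResult",
  function(x, disease = NULL, n = Inf) {
    df <- data.frame(
      disease = rep(x@diseases, times = length(x@mirnas)),
      mirna = rep(x@mirnas, each = length(x@diseases)),
      score = as.vector(x@fad),
      stringsAsFactors = FALSE
    )
    # per-disease rank, ties broken by miRNA label
    df <- df[order(df$disease, -df$score, df$mirna, method = "radix"), ]
    df$diseaseRank <- stats::ave(seq_len(nrow(df)), df$disease,
                                 FUN = seq_along)
    df <- df[order(-df$score, df$disease, df$mirna, method = "radix"), ]
    df$globalRank <- seq_len(nrow(df))
    rownames(df) <- NULL
    if (!is.null(disease)) {
      df <- df[normalizeLabel(df$disease) == normalizeLabel(disease), ]
      df <- df[order(df$diseaseRank), ]
      rownames(df) <- NULL
    }
    utils::head(df, n)
  })

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d diseases x %d miRNAs",
              length(object@diseases), length(object@mirnas)))
  if (!is.null(object@params$b)) cat(sprintf(", b = %d", object@params$b))
  cat("\n")
})

#' Run the whole prediction pipeline
#'
#' Restricts the two tables to their shared lncRNAs, builds the
#' incidence matrices and similarity bundle, assembles the tripartite
#' network, computes bounded shortest paths, distance coefficients and
#' the distance correlation matrix, and returns the similarity-smoothed
#' disease x miRNA scores. No miRNA-disease associations are used at
#' any point: the method is unsupervised.
#'
#' @param ld lncRNA-disease [AssociationTable-class].
#' @param lm lncRNA-miRNA [AssociationTable-class].
#' @param ontology optional [OntologyDAG-class] for the semantic
#'   similarity; without it the semantic matrix is zero off-diagonal.
#' @param b bandwidth (default 6).
#' @param distanceWeight `"as_printed"` or `"inverse"`, see
#'   [distanceCoefficients()].
#' @param slope,offset logistic constants, see [logisticTransform()].
#' @param keepIntermediates logical; attach incidences, similarities and
#'   the SPM/DCM/PM matrices to `params$details` of the result.
#' @return a [PredictionResult-class].
#' @export
predictAssociations <- function(ld, lm, ontology = NULL, b = 6L,
                                distanceWeight = c("as_printed", "inverse"),
                                slope = 15, offset = log(9999),
                                keepIntermediates = FALSE) {
  distanceWeight <- match.arg(distanceWeight)
  shared <- restrictToSharedLncrnas(ld, lm)
  lncs <- shared$ld@sourceNames
  kam1 <- incidenceMatrix(shared$ld, colOrder = lncs)
  kam2 <- incidenceMatrix(shared$lm, colOrder = lncs)
  sims <- buildSimilarities(kam1, kam2, dag = ontology,
                            slope = slope, offset = offset)
  net <- buildNetwork(kam1, kam2, b = b)
  spm <- shortestPaths(net)
  p <- distanceCoefficients(spm, b = b, weight = distanceWeight)
  dcm <- distanceCorrelationMatrix(p, spm, sims$fdd, sims$fll, sims$fmm,
                                   b = b)
  pmRes <- predictionMatrix(dcm, nrow(kam1), ncol(kam1), nrow(kam2))
  params <- list(b = as.integer(b), distanceWeight = distanceWeight,
                 slope = slope, offset = offset)
  if (keepIntermediates) {
    params$details <- list(kam1 = kam1, kam2 = kam2, similarities = sims,
                           network = net, spm = spm, p = p, dcm = dcm,
                           pm = pmRes$pm)
  }
  finalScores(sims$fdd, pmRes$c13, sims$fmm, params = params)
}
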