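# Independent oracles and small fixture builders used across the suite.

# breadth-first-search oracle for the bounded shortest-path matrix,
# via igraph::distances (independent of the package's matrix-power route)
bfsSpmOracle <- function(am, b) {
  g <- igraph::graph_from_adjacency_matrix((am != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  spm <- matrix(0L, nrow(am), ncol(am), dimnames = dimnames(am))
  within <- is.finite(d) & d >= 1 & d <= b
  spm[within] <- as.integer(d[within])
  diag(spm) <- 1L  # unit diagonal of the adjacency
  spm
}

# brute-force pairwise Mann-Whitney AUC (ties get half credit)
pairwiseAucOracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# semantic-contribution oracle: 0.5^(shortest child-to-parent path length
# from the target), computed with igraph on the reversed edges
semanticOracle <- function(dag, target) {
  e <- dagEdges(dag)
  g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                     vertices = dagNodes(dag))
  d <- igraph::distances(g, v = target, mode = "out")[1, ]
  d <- d[is.finite(d)]
  0.5^d
}

# random DAG on n nodes: edges only from later to earlier nodes in a
# fixed topological order, so acyclicity holds by construction
randomDag <- function(n, pEdge = 0.4) {
  nodes <- sprintf("t%02d", seq_len(n))
  ch <- character(); pa <- character()
  for (i in seq_len(n)[-1]) {
    parents <- which(stats::runif(i - 1) < pEdge)
    if (!length(parents)) parents <- sample.int(i - 1, 1)  # keep it rooted
    ch <- c(ch, rep(nodes[i], length(parents)))
    pa <- c(pa, nodes[parents])
  }
  ontologyDAG(data.frame(child = ch, parent = pa, stringsAsFactors = FALSE))
}

# random symmetric binary adjacency with unit diagonal
randomAdjacency <- function(n, pEdge = 0.15) {
  am <- matrix(0, n, n)
  up <- upper.tri(am)
  am[up] <- as.numeric(stats::runif(sum(up)) < pEdge)
  am <- am + t(am)
  diag(am) <- 1
  dimnames(am) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  am
}

# two-line association fixture builders
ldTable <- function(l, d) associationTable(l, d, role = "lncrna-disease")
lmTable <- function(l, m) associationTable(l, m, role = "lncrna-mirna")

writeTsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
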