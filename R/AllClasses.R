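#' @import methods
NULL

# ---------------------------------------------------------------------------
# Label normalization: trim, collapse internal whitespace, case-fold.
# Entities are compared on the normalized form; the first-seen original
# spelling is preserved for output.
# ---------------------------------------------------------------------------

normalizeLabel <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

.VALID_ROLES <- c("lncrna-disease", "lncrna-mirna", "mirna-disease")

#' AssociationTable: a deduplicated set of pairwise association records
#'
#' Stores binary association records between two entity classes
#' (for example lncRNA--disease pairs), together with ordered name
#' indices for the two sides. Labels are compared case-insensitively
#' after whitespace normalization; the first-seen spelling is kept.
#'
#' @slot records data.frame with columns `source`, `target`, `evidence`.
#' @slot role one of `"lncrna-disease"`, `"lncrna-mirna"`, `"mirna-disease"`.
#'   The source side is the first entity class named in the role, the
#'   target side the second.
#' @slot sourceNames,targetNames unique entity labels, ordered
#'   lexicographically by normalized label.
#' @slot metadata free-form list (e.g. harmonization drop reports).
#'
#' @exportClass AssociationTable
setClass("AssociationTable",
  slots = c(
    records = "data.frame",
    role = "character",
    sourceNames = "character",
    targetNames = "character",
    metadata = "list"
  )
)

setValidity("AssociationTable", function(object) {
  msg <- character()
  if (!identical(length(object@role), 1L) || !object@role %in% .VALID_ROLES) {
    msg <- c(msg, sprintf("role must be one of: %s",
                          paste(.VALID_ROLES, collapse = ", ")))
  }
  rec <- object@records
  if (!all(c("source", "target", "evidence") %in% names(rec))) {
    msg <- c(msg, "records must have columns source, target, evidence")
  } else {
    key <- paste(normalizeLabel(rec$source), normalizeLabel(rec$target),
                 sep = "\r")
    if (anyDuplicated(key)) {
      msg <- c(msg, "duplicate (source, target) pairs after normalization")
    }
    if (nrow(rec) > 0 &&
        (any(normalizeLabel(rec$source) == "") ||
         any(normalizeLabel(rec$target) == ""))) {
      msg <- c(msg, "empty labels are not allowed")
    }
    if (!all(normalizeLabel(rec$source) %in% normalizeLabel(object@sourceNames)))
      msg <- c(msg, "record source labels missing from sourceNames index")
    if (!all(normalizeLabel(rec$target) %in% normalizeLabel(object@targetNames)))
      msg <- c(msg, "record target labels missing from targetNames index")
  }
  if (length(msg)) msg else TRUE
})

#' OntologyDAG: a rooted directed acyclic graph of disease terms
#'
#' Nodes are identified by unique ids; `terms` maps each node id to a
#' (not necessarily unique) term label, so that a term occupying several
#' tree positions in a MeSH-style hierarchy can be represented either
#' collapsed (one node per term, the default of [readOntology()]) or
#' expanded (one node per position, as in the worked example returned by
#' [exampleDiseaseDAG()]).
#'
#' @slot nodes character vector of node ids.
#' @slot edges data.frame with columns `child`, `parent` (both node ids);
#'   edges point from more specific to more general terms.
#' @slot terms named character vector mapping node id to term label.
#'
#' @exportClass OntologyDAG
setClass("OntologyDAG",
  slots = c(nodes = "character", edges = "data.frame", terms = "character")
)

setValidity("OntologyDAG", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  e <- object@edges
  if (!all(c("child", "parent") %in% names(e))) {
    msg <- c(msg, "edges must have columns child, parent")
  } else if (nrow(e) > 0) {
    if (!all(e$child %in% object@nodes) || !all(e$parent %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
    if (.hasCycle(object@nodes, e))
      msg <- c(msg, "graph contains a cycle")
  }
  if (!all(object@nodes %in% names(object@terms)))
    msg <- c(msg, "terms map must cover every node")
  if (length(msg)) msg else TRUE
})

# Kahn's algorithm; TRUE if a cycle exists.
.hasCycle <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  removed <- 0L
  childrenOf <- split(edges$parent, edges$child)
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]
    removed <- removed + 1L
    for (p in childrenOf[[n]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  removed < length(nodes)
}

#' SimilarityMatrix: a labeled, symmetric similarity matrix
#'
#' @slot values square numeric matrix with identical row/column dimnames.
#' @slot kind tag naming the similarity, e.g. `"SSD"`, `"DGS"`, `"FDGS"`,
#'   `"MGS"`, `"LGS1"`, `"LGS2"`, `"FSD"`, `"FSM"`, `"FDD"`, `"FMM"`, `"FLL"`.
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  slots = c(values = "matrix", kind = "character")
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must be present and identical")
  if (any(!is.finite(v))) msg <- c(msg, "entries must be finite")
  if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-12)
    msg <- c(msg, "matrix must be symmetric (tolerance 1e-12)")
  if (length(msg)) msg else TRUE
})

#' TripartiteNetwork: diseases, lncRNAs and miRNAs with a block adjacency
#'
#' Node order is diseases, then lncRNAs, then miRNAs. The adjacency has a
#' unit diagonal; the only off-diagonal non-zero blocks are
#' disease--lncRNA and lncRNA--miRNA (no direct disease--disease,
#' miRNA--miRNA or disease--miRNA edges exist).
#'
#' @slot adjacency binary (D+L+M) square matrix, symmetric, unit diagonal.
#' @slot diseases,lncrnas,mirnas node labels per class, in matrix order.
#' @slot b positive integer bandwidth for bounded shortest paths.
#'
#' @exportClass TripartiteNetwork
setClass("TripartiteNetwork",
  slots = c(adjacency = "matrix", diseases = "character",
            lncrnas = "character", mirnas = "character", b = "integer")
)

setValidity("TripartiteNetwork", function(object) {
  am <- object@adjacency
  D <- length(object@diseases); L <- length(object@lncrnas)
  M <- length(object@mirnas); N <- D + L + M
  msg <- character()
  if (!identical(dim(am), c(N, N)))
    msg <- c(msg, "adjacency dimension does not match node counts")
  else {
    if (!all(am %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
    if (any(diag(am) != 1)) msg <- c(msg, "adjacency diagonal must be 1")
    if (!identical(am, t(am))) msg <- c(msg, "adjacency must be symmetric")
    dd <- am[seq_len(D), seq_len(D), drop = FALSE]
    mm <- am[D + L + seq_len(M), D + L + seq_len(M), drop = FALSE]
    dm <- am[seq_len(D), D + L + seq_len(M), drop = FALSE]
    if (D > 0 && any((dd - diag(D)) != 0))
      msg <- c(msg, "disease-disease block must be zero off-diagonal")
    if (M > 0 && any((mm - diag(M)) != 0))
      msg <- c(msg, "miRNA-miRNA block must be zero off-diagonal")
    if (D > 0 && M > 0 && any(dm != 0))
      msg <- c(msg, "disease-miRNA block must be zero")
  }
  if (length(object@b) != 1L || is.na(object@b) || object@b < 1L)
    msg <- c(msg, "b must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' PredictionResult: scored disease x miRNA association matrix
#'
#' @slot fad final D x M score matrix (similarity-smoothed).
#' @slot c13 the disease x miRNA block of the association-degree matrix,
#'   before smoothing.
#' @slot diseases,mirnas row/column labels.
#' @slot params list of pipeline parameters (b, distance weighting, ...).
#'
#' @exportClass PredictionResult
setClass("PredictionResult",
  slots = c(fad = "matrix", c13 = "matrix", diseases = "character",
            mirnas = "character", params = "list")
)

setValidity("PredictionResult", function(object) {
  msg <- character()
  D <- length(object@diseases); M <- length(object@mirnas)
  if (!identical(dim(object@fad), c(D, M)))
    msg <- c(msg, "fad dimension must be diseases x mirnas")
  if (!identical(dim(object@c13), c(D, M)))
    msg <- c(msg, "c13 dimension must be diseases x mirnas")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: LOOCV ranking evaluation summary
#'
#' @slot auc area under the ROC curve (Mann-Whitney, ties get half credit).
#' @slot roc data.frame with columns `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1).
#' @slot nPositives,nCandidates counts of gold and candidate pairs used.
#' @slot nDropped gold pairs excluded because their disease or miRNA is
#'   not in the score matrix.
#' @slot positiveRanks rank of each gold pair among all pairs
#'   (1 = highest score; ties averaged).
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  slots = c(auc = "numeric", roc = "data.frame", nPositives = "integer",
            nCandidates = "integer", nDropped = "integer",
            positiveRanks = "numeric")
)
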