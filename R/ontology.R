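# ---------------------------------------------------------------------------
# Disease ontology DAG: constructor, readers, traversal helpers.
# ---------------------------------------------------------------------------

#' Construct an OntologyDAG
#'
#' @param edges data.frame (or two-column matrix) of `(child, parent)`
#'   node ids; edges point from specific to general terms.
#' @param nodes optional extra node ids (isolated terms).
#' @param terms optional named character vector mapping node ids to term
#'   labels; defaults to the identity map. Several nodes may share a
#'   term label when a term occupies several positions of the hierarchy.
#' @return an [OntologyDAG-class].
#' @export
ontologyDAG <- function(edges, nodes = NULL, terms = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 && nrow(edges) > 0) stop("edges need child and parent columns")
  if (nrow(edges) > 0) {
    names(edges)[1:2] <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  allNodes <- unique(c(edges$child, edges$parent, nodes))
  if (is.null(terms)) terms <- stats::setNames(allNodes, allNodes)
  new("OntologyDAG", nodes = allNodes, edges = edges[c("child", "parent")],
      terms = terms)
}

#' @rdname OntologyDAG-class
#' @export
setMethod("dagNodes", "OntologyDAG", function(x) x@nodes)

#' @rdname OntologyDAG-class
#' @export
setMethod("dagEdges", "OntologyDAG", function(x) x@edges)

#' @rdname OntologyDAG-class
#' @export
setMethod("dagTerms", "OntologyDAG", function(x) x@terms)

#' @rdname OntologyDAG-class
#' @export
setMethod("dagRoots", "OntologyDAG", function(x) {
  setdiff(x@nodes, unique(x@edges$child))
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d nodes, %d edges, %d root(s)\n",
              length(object@nodes), nrow(object@edges),
              length(dagRoots(object))))
})

#' Read a disease ontology from TSV
#'
#' Two formats are supported. `"edge-list"`: each row is
#' `child<TAB>parent`. `"tree-number"`: each row is `term<TAB>code` in
#' MeSH tree-number style; the parent of code `X.Y` is the term holding
#' code `X` (e.g. `C04.588.274` hangs under `C04.588`), top-level codes
#' (no dot) are roots, and a term holding several codes gets the union
#' of the implied parents (positions are collapsed to one node per
#' term). Comment (`#`) and blank lines are skipped.
#'
#' @param path path to a UTF-8 TSV file.
#' @param format `"edge-list"` or `"tree-number"`.
#' @return an [OntologyDAG-class].
#' @export
readOntology <- function(path, format = c("edge-list", "tree-number")) {
  format <- match.arg(format)
  parsed <- .parseTsv(path, "ontology")
  fields <- parsed$fields
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: need 2 columns",
                 parsed$lineno[bad[1L]], path))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (format == "edge-list") {
    dag <- ontologyDAG(data.frame(child = a, parent = b,
                                  stringsAsFactors = FALSE))
  } else {
    termOfCode <- stats::setNames(a, b)
    parentCode <- sub("\\.[^.]+$", "", b)
    hasParent <- grepl(".", b, fixed = TRUE)
    dangling <- hasParent & !(parentCode %in% b)
    if (any(dangling)) {
      stop("dangling parent code ", parentCode[which(dangling)[1L]],
           " referenced by ", b[which(dangling)[1L]])
    }
    edges <- unique(data.frame(child = a[hasParent],
                               parent = unname(termOfCode[parentCode[hasParent]]),
                               stringsAsFactors = FALSE))
    edges <- edges[edges$child != edges$parent, , drop = FALSE]
    dag <- ontologyDAG(edges, nodes = unique(a))
  }
  validObject(dag)  # catches cycles
  dag
}

# children of `node` restricted to an optional node subset
.childrenOf <- function(dag, node, within = NULL) {
  ch <- dag@edges$child[dag@edges$parent == node]
  if (!is.null(within)) ch <- intersect(ch, within)
  ch
}

#' Ancestor closure of a node
#'
#' The node itself plus every node reachable by following child-to-parent
#' edges.
#'
#' @param dag an [OntologyDAG-class].
#' @param node a node id.
#' @return character vector of node ids.
#' @export
ancestorClosure <- function(dag, node) {
  if (!node %in% dag@nodes) stop("node not in DAG: ", node)
  parents <- split(dag@edges$parent, dag@edges$child)
  seen <- node
  frontier <- node
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}
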