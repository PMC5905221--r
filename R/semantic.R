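# ---------------------------------------------------------------------------
# Disease semantic similarity over a MeSH-style DAG.
#
# Each ancestor d of a target disease A contributes
#   D_A(A) = 1,   D_A(d) = 0.5 * max{ D_A(c) : c child of d within T(A) }
# where T(A) is A plus its ancestors. The semantic value of A is the sum
# of the contributions over T(A); similarity of two diseases is the
# shared contribution mass relative to the two semantic values.
# ---------------------------------------------------------------------------

#' Semantic contributions of a disease's ancestor terms
#'
#' Computes, for every node in the ancestor closure T(A) of `target`,
#' its contribution to the semantic value of A: the target contributes
#' 1, and each ancestor contributes 0.5 times the maximum contribution
#' of its children within T(A).
#'
#' @param dag an [OntologyDAG-class].
#' @param target a node id present in the DAG.
#' @return named numeric vector of contributions over T(A), with
#'   attribute `"target"`. All values lie in (0, 1]; the target maps to 1.
#' @seealso [semanticValue()], [termContributions()]
#' @export
semanticContributions <- function(dag, target) {
  stopifnot(is(dag, "OntologyDAG"))
  if (!target %in% dag@nodes) stop("target not in DAG: ", target)
  tset <- ancestorClosure(dag, target)
  vals <- stats::setNames(rep(NA_real_, length(tset)), tset)
  vals[target] <- 1
  # iterate to the DAG fixed point; each sweep finalizes at least one node
  remaining <- setdiff(tset, target)
  while (length(remaining)) {
    progressed <- FALSE
    for (d in remaining) {
      ch <- .childrenOf(dag, d, within = tset)
      cv <- vals[ch]
      if (length(cv) && !anyNA(cv)) {
        vals[d] <- 0.5 * max(cv)
        progressed <- TRUE
      }
    }
    remaining <- names(vals)[is.na(vals)]
    if (!progressed && length(remaining)) {
      stop("ancestor of ", target, " unreachable through children in T(A)")
    }
  }
  attr(vals, "target") <- target
  vals
}

#' Semantic value of a disease
#'
#' Sum of the ancestor contributions returned by
#' [semanticContributions()]; always >= 1 since the target contributes 1.
#'
#' @param contrib named numeric vector from [semanticContributions()].
#' @return a single number.
#' @export
semanticValue <- function(contrib) {
  sum(contrib)
}

#' Aggregate node contributions by term label
#'
#' When a term occupies several positions of the hierarchy (several DAG
#' nodes share one term label), this returns one contribution per term,
#' taking the maximum over that term's nodes.
#'
#' @param dag the [OntologyDAG-class] the contributions were computed on.
#' @param contrib output of [semanticContributions()].
#' @return named numeric vector keyed by term label.
#' @export
termContributions <- function(dag, contrib) {
  labels <- dag@terms[names(contrib)]
  vapply(split(as.numeric(contrib), labels), max, numeric(1))
}

#' Disease semantic similarity matrix
#'
#' For diseases i and j with ancestor closures T(i), T(j):
#' `SSD(i, j) = sum over shared nodes of (D_i(d) + D_j(d)) /
#' (semanticValue(i) + semanticValue(j))`. The diagonal is 1 and
#' diseases with disjoint ancestries score 0.
#'
#' Diseases absent from the DAG get 0 off-diagonal and 1 on the
#' diagonal, with a warning; upstream filtering normally removes them.
#'
#' @param dag an [OntologyDAG-class].
#' @param diseases ordered character vector of disease node ids.
#' @return a [SimilarityMatrix-class] of kind `"SSD"`.
#' @export
diseaseSemanticSimilarity <- function(dag, diseases) {
  stopifnot(is(dag, "OntologyDAG"), length(diseases) > 0)
  known <- diseases %in% dag@nodes
  if (!all(known)) {
    warning(sum(!known), " disease(s) not in the ontology; ",
            "their similarity rows are zero off-diagonal")
  }
  contribs <- vector("list", length(diseases))
  sv <- numeric(length(diseases))
  for (i in which(known)) {
    contribs[[i]] <- semanticContributions(dag, diseases[i])
    sv[i] <- semanticValue(contribs[[i]])
  }
  n <- length(diseases)
  ssd <- diag(1, n)
  dimnames(ssd) <- list(diseases, diseases)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!known[i]) next
      for (j in seq(i + 1, n)) {
        if (!known[j]) next
        shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
        if (length(shared)) {
          ssd[i, j] <- ssd[j, i] <-
            sum(contribs[[i]][shared] + contribs[[j]][shared]) /
            (sv[i] + sv[j])
        }
      }
    }
  }
  similarityMatrix(ssd, kind = "SSD")
}
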