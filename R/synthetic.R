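# ---------------------------------------------------------------------------
# Synthetic tripartite networks with planted block signal, plus the
# worked ontology example.
# ---------------------------------------------------------------------------

#' Configuration for the synthetic tripartite generator
#'
#' Diseases, lncRNAs and miRNAs are partitioned into `nBlocks`
#' communities with heterogeneous sizes (proportional to 1:2:...:k,
#' mirroring the skewed community sizes of real association data).
#' lncRNA-disease and lncRNA-miRNA edges are Bernoulli draws with
#' probability `pIn` inside a matched block and `pOut` across blocks;
#' the planted truth is the set of same-block disease-miRNA pairs.
#'
#' @param nDiseases,nLncrnas,nMirnas entity counts (each >= 1).
#' @param nBlocks planted community count, at most the smallest entity
#'   count.
#' @param pIn,pOut within/between-block edge probabilities in \[0, 1\],
#'   `pIn >= pOut` (equality gives the null model with no signal).
#' @param dagDepth number of ancestor levels between a block's diseases
#'   and the shared root of the generated ontology.
#' @param dagBranching number of sibling parent terms the diseases of a
#'   block are spread over at the deepest level.
#' @param seed optional integer seed; the generator draws all edges from
#'   one RNG stream (disease-lncRNA first, then lncRNA-miRNA, both in
#'   column-major order), so outputs are reproducible from the seed.
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nDiseases = 30L, nLncrnas = 40L, nMirnas = 30L,
                            nBlocks = 3L, pIn = 0.9, pOut = 0.05,
                            dagDepth = 3L, dagBranching = 2L, seed = NULL) {
  cfg <- list(nDiseases = as.integer(nDiseases),
              nLncrnas = as.integer(nLncrnas),
              nMirnas = as.integer(nMirnas),
              nBlocks = as.integer(nBlocks),
              pIn = pIn, pOut = pOut,
              dagDepth = as.integer(dagDepth),
              dagBranching = as.integer(dagBranching),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  with(cfg, {
    stopifnot(nDiseases >= 1, nLncrnas >= 1, nMirnas >= 1, nBlocks >= 1,
              nBlocks <= min(nDiseases, nLncrnas, nMirnas),
              pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1, pIn >= pOut,
              dagDepth >= 1, dagBranching >= 1)
  })
  structure(cfg, class = "SyntheticConfig")
}

# allocate n items to k near-equal blocks (first n %% k blocks get the
# remainder); equal sizes keep the null model (pIn == pOut) calibrated
# at AUC 0.5 under pooled ranking
.blockSizes <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  as.integer(base)
}

.blockLabels <- function(n, k) rep(seq_len(k), times = .blockSizes(n, k))

.bernoulliIncidence <- function(rowBlocks, colBlocks, pIn, pOut,
                                rowNames, colNames) {
  p <- ifelse(outer(rowBlocks, colBlocks, "=="), pIn, pOut)
  m <- matrix(as.numeric(stats::runif(length(p)) < p),
              nrow = length(rowBlocks),
              dimnames = list(rowNames, colNames))
  m
}

.blockOntology <- function(diseaseNames, diseaseBlocks, depth, branching) {
  edges <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  root <- "disease root"
  for (k in sort(unique(diseaseBlocks))) {
    chain <- sprintf("block %d ancestor %d", k, seq_len(depth))
    edges <- rbind(edges, data.frame(
      child = chain, parent = c(chain[-1], root)[seq_len(depth)] ,
      stringsAsFactors = FALSE))
    # depth-1 chain above the leaves, branching sibling parents below it
    groups <- sprintf("block %d group %d", k, seq_len(branching))
    edges <- rbind(edges, data.frame(child = groups, parent = chain[1],
                                     stringsAsFactors = FALSE))
    members <- diseaseNames[diseaseBlocks == k]
    edges <- rbind(edges, data.frame(
      child = members,
      parent = groups[(seq_along(members) - 1L) %% branching + 1L],
      stringsAsFactors = FALSE))
  }
  ontologyDAG(edges)
}

#' Generate a synthetic tripartite dataset with planted signal
#'
#' Produces a disease ontology, a lncRNA-disease table, a lncRNA-miRNA
#' table and a gold miRNA-disease table. Same-block diseases share a
#' deep common ancestor in the ontology while cross-block diseases meet
#' only at the root; the gold pairs (all same-block disease-miRNA
#' pairs) are the planted truth and are never fed to the predictor.
#' If the drawn tables share no lncRNA the draw is repeated once from
#' the same stream before failing.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements `ontology` ([OntologyDAG-class]),
#'   `lncDisease`, `lncMirna`, `gold` ([AssociationTable-class]s),
#'   `blocks` (per-class block assignments) and `config`.
#' @export
generateTripartite <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(config$seed)
  }
  dNames <- sprintf("disease%02d", seq_len(config$nDiseases))
  lNames <- sprintf("lnc%02d", seq_len(config$nLncrnas))
  mNames <- sprintf("mir%02d", seq_len(config$nMirnas))
  dBlocks <- .blockLabels(config$nDiseases, config$nBlocks)
  lBlocks <- .blockLabels(config$nLncrnas, config$nBlocks)
  mBlocks <- .blockLabels(config$nMirnas, config$nBlocks)

  drawOnce <- function() {
    kam1 <- .bernoulliIncidence(dBlocks, lBlocks, config$pIn, config$pOut,
                                dNames, lNames)
    kam2 <- .bernoulliIncidence(mBlocks, lBlocks, config$pIn, config$pOut,
                                mNames, lNames)
    list(kam1 = kam1, kam2 = kam2)
  }
  toTables <- function(draw) {
    e1 <- which(draw$kam1 == 1, arr.ind = TRUE)
    e2 <- which(draw$kam2 == 1, arr.ind = TRUE)
    if (!nrow(e1) || !nrow(e2)) return(NULL)
    ld <- associationTable(lNames[e1[, 2]], dNames[e1[, 1]],
                           role = "lncrna-disease")
    lm <- associationTable(lNames[e2[, 2]], mNames[e2[, 1]],
                           role = "lncrna-mirna")
    if (!length(intersect(ld@sourceNames, lm@sourceNames))) return(NULL)
    list(ld = ld, lm = lm)
  }
  tables <- toTables(drawOnce())
  if (is.null(tables)) tables <- toTables(drawOnce())
  if (is.null(tables)) {
    stop("generated tables share no lncRNA even after one regeneration; ",
         "increase sizes or edge probabilities")
  }
  goldPairs <- which(outer(mBlocks, dBlocks, "=="), arr.ind = TRUE)
  gold <- associationTable(mNames[goldPairs[, 1]], dNames[goldPairs[, 2]],
                           role = "mirna-disease")
  list(
    ontology = .blockOntology(dNames, dBlocks, config$dagDepth,
                              config$dagBranching),
    lncDisease = tables$ld,
    lncMirna = tables$lm,
    gold = gold,
    blocks = list(disease = stats::setNames(dBlocks, dNames),
                  lncrna = stats::setNames(lBlocks, lNames),
                  mirna = stats::setNames(mBlocks, mNames)),
    config = config
  )
}

#' Worked ancestor DAG of Gastrointestinal Neoplasms
#'
#' Encodes the MeSH ancestor graph of 'Gastrointestinal Neoplasms' with
#' one node per tree position: the term 'Digestive System Neoplasms'
#' holds two tree numbers (C04.588.274 under the Neoplasms branch and
#' C06.301 under Digestive System Diseases) and therefore appears as
#' two nodes, so the DAG has seven nodes. Node ids are the tree-number
#' codes (the target keeps its term name); the `terms` map carries the
#' term labels. The ancestor contributions of the target are
#' 1, 0.5, 0.5, 0.5, 0.25, 0.25 and 0.125, summing to a semantic value
#' of 3.125.
#'
#' @return list with elements `dag` (an [OntologyDAG-class]) and
#'   `target` (the node id of 'Gastrointestinal Neoplasms').
#' @examples
#' ex <- exampleDiseaseDAG()
#' contrib <- semanticContributions(ex$dag, ex$target)
#' semanticValue(contrib)                       # 3.125
#' termContributions(ex$dag, contrib)["Neoplasms"]  # 0.125
#' @export
exampleDiseaseDAG <- function() {
  target <- "Gastrointestinal Neoplasms"
  edges <- data.frame(
    child = c(target, target, target,
              "C04.588.274", "C06.301", "C06.405", "C04.588"),
    parent = c("C04.588.274", "C06.301", "C06.405",
               "C04.588", "C06", "C06", "C04"),
    stringsAsFactors = FALSE
  )
  terms <- c(
    "Gastrointestinal Neoplasms" = "Gastrointestinal Neoplasms",
    "C04.588.274" = "Digestive System Neoplasms",
    "C06.301" = "Digestive System Neoplasms",
    "C06.405" = "Gastrointestinal Diseases",
    "C04.588" = "Neoplasms by Site",
    "C06" = "Digestive System Diseases",
    "C04" = "Neoplasms"
  )
  list(dag = ontologyDAG(edges, terms = terms), target = target)
}
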