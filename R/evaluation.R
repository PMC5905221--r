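# ---------------------------------------------------------------------------
# LOOCV ranking evaluation: pooled ROC / AUC against a gold table.
# ---------------------------------------------------------------------------

#' @rdname EvaluationReport-class
#' @export
setMethod("auc", "EvaluationReport", function(x) x@auc)

#' @rdname EvaluationReport-class
#' @export
setMethod("rocPoints", "EvaluationReport", function(x) x@roc)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport: AUC = %.4f (%d positives vs %d candidates%s)\n",
    object@auc, object@nPositives, object@nCandidates,
    if (object@nDropped > 0)
      sprintf(", %d gold pair(s) dropped", object@nDropped) else ""))
})

# Mann-Whitney AUC with half credit for ties, via midranks.
.mannWhitneyAuc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# ROC polyline from pooled scores: one vertex per distinct threshold,
# so tied scores produce a diagonal segment (matching half-tie credit).
.rocCurve <- function(scoreVec, isPos) {
  ord <- order(scoreVec, decreasing = TRUE)
  pos <- isPos[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(scoreVec[ord], fromLast = TRUE)  # end of tie groups
  data.frame(
    fpr = c(0, fp[last] / sum(!isPos)),
    tpr = c(0, tp[last] / sum(isPos))
  )
}

#' Trapezoid area under an ROC polyline
#'
#' @param roc data.frame with columns `fpr`, `tpr` (non-decreasing).
#' @return the area, in \[0, 1\].
#' @export
trapezoidAuc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Leave-one-out ranking evaluation of a score matrix
#'
#' Because the predictor never consumes miRNA-disease associations,
#' leaving a gold pair out does not change the scores, so they are
#' computed once and each gold pair is ranked against all pairs without
#' gold evidence, pooled over every disease. The AUC is the normalized
#' Mann-Whitney statistic between gold-pair and candidate-pair scores,
#' with ties counted as half, and coincides with the trapezoid area
#' under the reported ROC curve.
#'
#' @param pred a [PredictionResult-class] or a scored disease x miRNA
#'   matrix with dimnames.
#' @param gold an [AssociationTable-class] with role `"mirna-disease"`.
#'   Pairs whose disease or miRNA is absent from the score matrix are
#'   dropped and counted in the report.
#' @return an [EvaluationReport-class].
#' @seealso [macroAucByDisease()] for the per-disease secondary metric.
#' @export
loocvAuc <- function(pred, gold) {
  fad <- if (is(pred, "PredictionResult")) scores(pred) else as.matrix(pred)
  stopifnot(is(gold, "AssociationTable"))
  if (gold@role != "mirna-disease") stop("gold must have role mirna-disease")
  di <- match(normalizeLabel(gold@records$target),
              normalizeLabel(rownames(fad)))
  mi <- match(normalizeLabel(gold@records$source),
              normalizeLabel(colnames(fad)))
  usable <- !is.na(di) & !is.na(mi)
  nDropped <- sum(!usable)
  if (nDropped > 0) {
    message(nDropped, " gold pair(s) dropped: entity not in score matrix")
  }
  if (!any(usable)) stop("zero usable gold pairs")
  posMask <- matrix(FALSE, nrow(fad), ncol(fad))
  posMask[cbind(di[usable], mi[usable])] <- TRUE
  scoreVec <- as.vector(fad)
  isPos <- as.vector(posMask)
  if (all(isPos)) stop("gold covers every pair; no candidates to rank against")
  aucVal <- .mannWhitneyAuc(scoreVec[isPos], scoreVec[!isPos])
  ranksHighFirst <- rank(-scoreVec)
  new("EvaluationReport",
      auc = aucVal,
      roc = .rocCurve(scoreVec, isPos),
      nPositives = sum(isPos),
      nCandidates = sum(!isPos),
      nDropped = as.integer(nDropped),
      positiveRanks = ranksHighFirst[isPos])
}

#' Per-disease macro-averaged ranking AUC
#'
#' Secondary metric (not part of the pooled evaluation protocol):
#' computes one Mann-Whitney AUC per disease having at least one gold
#' and one candidate miRNA, and averages them.
#'
#' @inheritParams loocvAuc
#' @return a list with `macroAuc` and the per-disease `perDisease`
#'   data.frame.
#' @export
macroAucByDisease <- function(pred, gold) {
  fad <- if (is(pred, "PredictionResult")) scores(pred) else as.matrix(pred)
  stopifnot(is(gold, "AssociationTable"), gold@role == "mirna-disease")
  di <- match(normalizeLabel(gold@records$target),
              normalizeLabel(rownames(fad)))
  mi <- match(normalizeLabel(gold@records$source),
              normalizeLabel(colnames(fad)))
  usable <- !is.na(di) & !is.na(mi)
  posMask <- matrix(FALSE, nrow(fad), ncol(fad))
  posMask[cbind(di[usable], mi[usable])] <- TRUE
  per <- lapply(seq_len(nrow(fad)), function(i) {
    p <- posMask[i, ]
    if (any(p) && any(!p)) .mannWhitneyAuc(fad[i, p], fad[i, !p]) else NA_real_
  })
  per <- data.frame(disease = rownames(fad), auc = unlist(per))
  list(macroAuc = mean(per$auc, na.rm = TRUE), perDisease = per)
}

#' Bandwidth sensitivity sweep
#'
#' Recomputes the full pipeline for each bandwidth value and evaluates
#' it by [loocvAuc()] against the gold table.
#'
#' @inheritParams predictAssociations
#' @param gold gold-standard `"mirna-disease"` [AssociationTable-class].
#' @param bValues integer vector of bandwidths, each >= 1.
#' @return data.frame with columns `b` and `auc`.
#' @export
bSweep <- function(ld, lm, gold, bValues, ontology = NULL,
                   distanceWeight = c("as_printed", "inverse"), ...) {
  stopifnot(length(bValues) >= 1, all(bValues >= 1))
  distanceWeight <- match.arg(distanceWeight)
  aucs <- vapply(bValues, function(b) {
    pred <- predictAssociations(ld, lm, ontology = ontology, b = b,
                                distanceWeight = distanceWeight, ...)
    auc(loocvAuc(pred, gold))
  }, numeric(1))
  data.frame(b = as.integer(bValues), auc = aucs)
}
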