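#' @rdname AssociationTable-class
#' @param x an object
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname AssociationTable-class
#' @export
setGeneric("tableRole", function(x) standardGeneric("tableRole"))

#' @rdname AssociationTable-class
#' @export
setGeneric("sourceNames", function(x) standardGeneric("sourceNames"))

#' @rdname AssociationTable-class
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))

#' @rdname AssociationTable-class
#' @export
setGeneric("nAssociations", function(x) standardGeneric("nAssociations"))

#' @rdname SimilarityMatrix-class
#' @param x an object
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname OntologyDAG-class
#' @param x an object
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @rdname OntologyDAG-class
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))

#' @rdname OntologyDAG-class
#' @export
setGeneric("dagTerms", function(x) standardGeneric("dagTerms"))

#' @rdname OntologyDAG-class
#' @export
setGeneric("dagRoots", function(x) standardGeneric("dagRoots"))

#' @rdname PredictionResult-class
#' @param x an object
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PredictionResult-class
#' @param ... further arguments
#' @export
setGeneric("rankedPairs", function(x, ...) standardGeneric("rankedPairs"))

#' @rdname EvaluationReport-class
#' @param x an object
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
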