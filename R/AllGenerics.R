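#' @include AllClasses.R
NULL

#' @rdname SimilarityNetwork-class
#' @param x a `SimilarityNetwork`
#' @export
setGeneric("repnodes", function(x) standardGeneric("repnodes"))

#' @rdname SimilarityNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SimilarityNetwork-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname SimilarityNetwork-class
#' @export
setGeneric("networkCutoff", function(x) standardGeneric("networkCutoff"))

#' @rdname PairDataset-class
#' @param x a `PairDataset`
#' @param ... ignored
#' @export
setGeneric("pairs", function(x) standardGeneric("pairs"))

#' @rdname PairDataset-class
#' @export
setGeneric("activeFraction", function(x) standardGeneric("activeFraction"))

#' @rdname EvaluationReport-class
#' @param x an `EvaluationReport`
#' @export
setGeneric("runMetrics", function(x) standardGeneric("runMetrics"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))

#' @rdname PredictionMatrix-class
#' @param x a `PredictionMatrix`
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname PredictionMatrix-class
#' @export
setGeneric("binaryCalls", function(x) standardGeneric("binaryCalls"))

#' @rdname ActiveSiteProfile-class
#' @param x an `ActiveSiteProfile`
#' @export
setGeneric("siteResidues", function(x) standardGeneric("siteResidues"))
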