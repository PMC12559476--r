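#' @include AllGenerics.R
NULL

## ---- SimilarityNetwork ----

#' @rdname SimilarityNetwork-class
#' @export
setMethod("repnodes", "SimilarityNetwork", function(x) x@repnodes)

#' @rdname SimilarityNetwork-class
#' @export
setMethod("networkEdges", "SimilarityNetwork", function(x) x@edges)

#' @rdname SimilarityNetwork-class
#' @export
setMethod("clusterTable", "SimilarityNetwork", function(x) x@clusters)

#' @rdname SimilarityNetwork-class
#' @export
setMethod("networkCutoff", "SimilarityNetwork", function(x) x@cutoff)

setMethod("show", "SimilarityNetwork", function(object) {
  nmem <- length(unlist(object@repnodes$members, use.names = FALSE))
  cat(sprintf(
    "SimilarityNetwork: %d sequences in %d repnodes, %d edges, %d clusters\n",
    nmem, nrow(object@repnodes), nrow(object@edges),
    length(unique(object@clusters$cluster_id))))
  cat(sprintf("  identity cutoff %.2f, repnode threshold %.2f\n",
              object@cutoff, object@repnodeThreshold))
})

## ---- PairDataset ----

#' @rdname PairDataset-class
#' @export
setMethod("pairs", "PairDataset", function(x) x@pairs)

#' @rdname PairDataset-class
#' @export
setMethod("activeFraction", "PairDataset", function(x) mean(x@pairs$label == 1L))

#' @rdname PairDataset-class
#' @export
setMethod("length", "PairDataset", function(x) nrow(x@pairs))

setMethod("show", "PairDataset", function(object) {
  p <- object@pairs
  cat(sprintf(
    "PairDataset (%s): %d pairs, %d enzymes x %d substrates, %.1f%% active\n",
    object@provenance, nrow(p), length(unique(p$enzyme_id)),
    length(unique(p$substrate_id)), 100 * mean(p$label == 1L)))
})

## ---- EvaluationReport ----

#' @rdname EvaluationReport-class
#' @export
setMethod("runMetrics", "EvaluationReport", function(x) x@metrics)

#' @rdname EvaluationReport-class
#' @export
setMethod("metricSummary", "EvaluationReport", function(x) {
  m <- x@metrics
  data.frame(
    metric = c("accuracy", "f1"),
    mean = c(mean(m$accuracy), mean(m$f1, na.rm = TRUE)),
    sd = c(stats::sd(m$accuracy), stats::sd(m$f1, na.rm = TRUE)),
    n_runs = nrow(m)
  )
})

setMethod("show", "EvaluationReport", function(object) {
  s <- metricSummary(object)
  cat(sprintf("EvaluationReport: %s, %d runs\n",
              object@config@classifier, s$n_runs[1]))
  cat(sprintf("  accuracy %.3f +/- %.3f | F1 %.3f +/- %.3f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
})

## ---- PredictionMatrix ----

#' @rdname PredictionMatrix-class
#' @export
setMethod("probabilities", "PredictionMatrix", function(x) x@probabilities)

#' @rdname PredictionMatrix-class
#' @export
setMethod("binaryCalls", "PredictionMatrix", function(x) x@calls)

setMethod("show", "PredictionMatrix", function(object) {
  cat(sprintf(
    "PredictionMatrix: %d enzymes x %d substrates, mean over %d runs, threshold %.2f\n",
    nrow(object@probabilities), ncol(object@probabilities),
    object@nRuns, object@threshold))
  cat(sprintf("  %.1f%% of cells called active\n", 100 * mean(object@calls)))
})

## ---- ActiveSiteProfile ----

#' @rdname ActiveSiteProfile-class
#' @export
setMethod("siteResidues", "ActiveSiteProfile", function(x) x@residues)

setMethod("show", "ActiveSiteProfile", function(object) {
  cat(sprintf("ActiveSiteProfile: %d sequences x %d reference positions\n",
              nrow(object@residues), ncol(object@residues)))
  if (length(object@groups))
    cat(sprintf("  %d groups\n", length(unique(object@groups))))
})

setMethod("show", "ActiveSitePositionMap", function(object) {
  cat(sprintf("ActiveSitePositionMap: reference '%s' (%d aa), %d positions\n",
              names(object@reference), Biostrings::width(object@reference),
              nrow(object@positions)))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %s | %d-fold x %d repeats | %d prediction runs | seed %d | threshold %.2f\n",
    object@classifier, object@cvFolds, object@cvRepeats,
    object@nPredictionRuns, object@baseSeed, object@decisionThreshold))
})
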