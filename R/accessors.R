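## Accessors and show() methods. Downstream code goes through these rather
## than reaching into slots.

#' @describeIn CooccurrenceTable-class counts matrix accessor
#' @param x,object a \code{CooccurrenceTable}
#' @export
setGeneric("cooccurrenceCounts", function(x) standardGeneric("cooccurrenceCounts"))
#' @export
setMethod("cooccurrenceCounts", "CooccurrenceTable", function(x) x@counts)

#' @describeIn CooccurrenceTable-class LMI weight matrix accessor (NULL
#'   until \code{\link{computeLMI}} has been run)
#' @export
setGeneric("lmiWeights", function(x) standardGeneric("lmiWeights"))
#' @export
setMethod("lmiWeights", "CooccurrenceTable", function(x) x@weighted)

#' @describeIn CooccurrenceTable-class slice name accessor
#' @export
setGeneric("sliceName", function(x) standardGeneric("sliceName"))
#' @export
setMethod("sliceName", "CooccurrenceTable", function(x) x@sliceName)
#' @export
setMethod("sliceName", "TopicModel", function(x) x@sliceName)

#' @describeIn TopicModel-class number of topics
#' @param x,object a \code{TopicModel}
#' @export
setGeneric("nTopics", function(x) standardGeneric("nTopics"))
#' @export
setMethod("nTopics", "TopicModel", function(x) x@nTopics)

#' @describeIn TopicModel-class P(topic | context word) matrix
#' @export
setGeneric("contextTopic", function(x) standardGeneric("contextTopic"))
#' @export
setMethod("contextTopic", "TopicModel", function(x) x@contextTopic)

#' @describeIn TopicModel-class P(target word | topic) matrix
#' @export
setGeneric("topicTarget", function(x) standardGeneric("topicTarget"))
#' @export
setMethod("topicTarget", "TopicModel", function(x) x@topicTarget)

#' @describeIn TopicModel-class marginal P(topic)
#' @export
setGeneric("topicPrior", function(x) standardGeneric("topicPrior"))
#' @export
setMethod("topicPrior", "TopicModel", function(x) x@topicPrior)

#' Probability vector of a distribution-like object
#'
#' @param x a \code{TopicDistribution} or \code{Blend}
#' @return numeric simplex vector over topics
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
#' @rdname probs
#' @export
setMethod("probs", "TopicDistribution", function(x) x@probs)
#' @rdname probs
#' @export
setMethod("probs", "Blend", function(x) x@probs)

#' @describeIn CompletionSet-class response counts accessor
#' @param x,object a \code{CompletionSet}
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @export
setMethod("responses", "CompletionSet", function(x) x@responses)

#' @describeIn CompletionSet-class inclusion flag (at least 4 responses)
#' @export
setGeneric("isIncluded", function(x) standardGeneric("isIncluded"))
#' @export
setMethod("isIncluded", "CompletionSet", function(x) x@included)

#' Dissimilarity matrix of an RDM
#' @param x an \code{RDM}
#' @export
setGeneric("rdmMatrix", function(x) standardGeneric("rdmMatrix"))
#' @rdname rdmMatrix
#' @export
setMethod("rdmMatrix", "RDM", function(x) x@d)

#' Labels of an RDM
#' @param x an \code{RDM}
#' @export
setGeneric("rdmLabels", function(x) standardGeneric("rdmLabels"))
#' @rdname rdmLabels
#' @export
setMethod("rdmLabels", "RDM", function(x) x@labels)

#' Lower-triangle vector of an RDM (column-wise, the pair order used
#' throughout the package)
#' @param x an \code{RDM}
#' @export
setGeneric("rdmVector", function(x) standardGeneric("rdmVector"))
#' @rdname rdmVector
#' @export
setMethod("rdmVector", "RDM", function(x) x@d[lower.tri(x@d)])

#' @describeIn SourceEpochs-class data array accessor
#' @param x,object a \code{SourceEpochs}
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @export
setMethod("epochData", "SourceEpochs", function(x) x@data)

#' @describeIn SourceEpochs-class trial id accessor
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @export
setMethod("trialIds", "SourceEpochs", function(x) x@trialIds)

#' Time axis in ms
#' @param x a \code{SourceEpochs}, \code{SearchlightIndex} or
#'   \code{ClusterResult}
#' @export
setGeneric("timeMs", function(x) standardGeneric("timeMs"))
#' @rdname timeMs
#' @export
setMethod("timeMs", "SourceEpochs", function(x) x@timeMs)
#' @rdname timeMs
#' @export
setMethod("timeMs", "SearchlightIndex", function(x) x@timeMs)
#' @rdname timeMs
#' @export
setMethod("timeMs", "ClusterResult", function(x) x@timeMs)

#' @describeIn CorticalMesh-class vertex coordinates (mm)
#' @param x,object a \code{CorticalMesh}
#' @export
setGeneric("meshCoords", function(x) standardGeneric("meshCoords"))
#' @export
setMethod("meshCoords", "CorticalMesh", function(x) x@coords)

#' @describeIn CorticalMesh-class undirected edge matrix
#' @export
setGeneric("meshEdges", function(x) standardGeneric("meshEdges"))
#' @export
setMethod("meshEdges", "CorticalMesh", function(x) x@edges)

#' @describeIn ClusterResult-class list of clusters (members, mass, p)
#' @param x,object a \code{ClusterResult}
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @export
setMethod("clusters", "ClusterResult", function(x) x@clusters)

#' @describeIn SearchlightMap-class fits array (subjects x vertices x time)
#' @param x,object a \code{SearchlightMap}
#' @export
setGeneric("fitMaps", function(x) standardGeneric("fitMaps"))
#' @export
setMethod("fitMaps", "SearchlightMap", function(x) x@fits)

#' @describeIn TMap-class t matrix accessor
#' @param x,object a \code{TMap}
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))
#' @export
setMethod("tValues", "TMap", function(x) x@t)

setMethod("show", "CooccurrenceTable", function(object) {
  cat(sprintf("CooccurrenceTable slice '%s': %d contexts x %d targets, total count %g%s\n",
              object@sliceName, nrow(object@counts), ncol(object@counts),
              sum(object@counts),
              if (is.null(object@weighted)) " (unweighted)" else " (LMI-weighted)"))
})

setMethod("show", "TopicModel", function(object) {
  cat(sprintf("TopicModel slice '%s': %d topics, %d contexts, %d targets (%s, seed %s)\n",
              object@sliceName, object@nTopics, nrow(object@contextTopic),
              ncol(object@topicTarget),
              object@trainingConfig$method %||% "?",
              format(object@trainingConfig$seed %||% NA)))
})

setMethod("show", "CompletionSet", function(object) {
  cat(sprintf("CompletionSet %s [%s]: %d responses over %d words (%s)\n",
              object@stimulusId, object@stage, object@nTotal,
              length(object@responses),
              if (object@included) "included" else "excluded: <4 responses"))
})

setMethod("show", "Blend", function(object) {
  cat(sprintf("Blend %s [%s]: %d topics, %d contributing words, entropy %.3f nats\n",
              object@stimulusId, object@modelName, length(object@probs),
              length(object@contributingWords),
              weightedEntropy(object@probs, rep(1, length(object@probs)))))
})

setMethod("show", "RDM", function(object) {
  cat(sprintf("%s RDM over %d items (mean off-diagonal %.4f)\n",
              object@kind, length(object@labels),
              mean(object@d[lower.tri(object@d)])))
})

setMethod("show", "CorticalMesh", function(object) {
  cat(sprintf("CorticalMesh: %d vertices, %d edges\n",
              nrow(object@coords), nrow(object@edges)))
})

setMethod("show", "SourceEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("SourceEpochs subject %s [%s]: %d trials x %d vertices x %d samples (%g-%g ms)\n",
              object@subjectId, object@epochName, d[1], d[2], d[3],
              min(object@timeMs), max(object@timeMs)))
})

setMethod("show", "SearchlightIndex", function(object) {
  cat(sprintf("SearchlightIndex: %d vertices, r = %g mm / %g ms (+/-%d samples)\n",
              length(object@spatialMembers), object@rMm, object@rMs,
              object@halfwin))
})

setMethod("show", "SearchlightMap", function(object) {
  d <- dim(object@fits)
  cat(sprintf("SearchlightMap [%s]: %d subjects x %d vertices x %d samples\n",
              object@modelName, d[1], d[2], d[3]))
})

setMethod("show", "TMap", function(object) {
  cat(sprintf("TMap (%s-tailed, df = %d): max t = %.3f\n",
              object@tail, object@df, suppressWarnings(max(object@t, na.rm = TRUE))))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s), CFT p = %g (t >= %.3f), %d permutations\n",
              length(object@clusters), object@cftP, object@tThreshold,
              object@nPerm))
  for (i in seq_along(object@clusters)) {
    cl <- object@clusters[[i]]
    cat(sprintf("  #%d: %d points, mass %.2f, p = %.4g\n",
                i, nrow(cl$members), cl$mass, cl$p))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
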