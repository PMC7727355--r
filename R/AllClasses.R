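## S4 classes for the blendRSA pipeline. Validity methods enforce the
## contracts the downstream algebra relies on (simplex-valued
## distributions, symmetric zero-diagonal RDMs, aligned array shapes).

.SIMPLEX_TOL <- 1e-9

.checkSimplexRows <- function(m, what, tol = .SIMPLEX_TOL) {
  if (any(m < -tol)) return(sprintf("%s has negative entries", what))
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    return(sprintf("%s rows must sum to 1 (max |deviation| %.3g)",
                   what, max(abs(rs - 1))))
  NULL
}

#' CooccurrenceTable: co-occurrence counts for one tensor slice
#'
#' Holds context-by-target co-occurrence counts for one syntactic slice of
#' a corpus tensor (\code{"SN_V"}: subject nouns against verbs;
#' \code{"SNV_CN"}: subject nouns and verbs against complement nouns),
#' optionally with local-mutual-information weights of the same shape.
#'
#' @slot sliceName slice identifier, typically \code{"SN_V"} or
#'   \code{"SNV_CN"}.
#' @slot counts non-negative numeric matrix, contexts in rows, targets in
#'   columns, with unique dimnames.
#' @slot weighted \code{NULL}, or a non-negative LMI weight matrix of the
#'   same shape (filled by \code{\link{computeLMI}}).
#' @seealso \code{\link{computeLMI}}, \code{\link{trainTopicModel}}
#' @export
setClass("CooccurrenceTable",
  representation(sliceName = "character", counts = "matrix",
                 weighted = "ANY"),
  prototype(weighted = NULL),
  validity = function(object) {
    msg <- character()
    cm <- object@counts
    if (!is.numeric(cm)) msg <- c(msg, "counts must be numeric")
    if (any(cm < 0)) msg <- c(msg, "counts must be non-negative")
    dn <- dimnames(cm)
    if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
      msg <- c(msg, "counts must have row (context) and column (target) names")
    else {
      if (anyDuplicated(dn[[1]])) msg <- c(msg, "duplicate context words")
      if (anyDuplicated(dn[[2]])) msg <- c(msg, "duplicate target words")
    }
    if (!is.null(object@weighted)) {
      w <- object@weighted
      if (!identical(dim(w), dim(cm)))
        msg <- c(msg, "weighted must match the shape of counts")
      else if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' TopicModel: trained topic representation for one tensor slice
#'
#' Posterior-mean multinomials of an LDA model in which each context word is
#' one "document" and its (weighted) targets are the tokens.
#'
#' @slot sliceName slice the model was trained on.
#' @slot nTopics number of topics (>= 1).
#' @slot contextTopic matrix of P(topic | context word); one simplex row per
#'   context word.
#' @slot topicTarget matrix of P(target word | topic); one simplex row per
#'   topic, target words in columns.
#' @slot topicPrior strictly positive marginal P(topic), summing to 1.
#' @slot trainingConfig list of hyperparameters, iteration count and seed.
#' @seealso \code{\link{trainTopicModel}},
#'   \code{\link{wordTopicDistribution}}
#' @export
setClass("TopicModel",
  representation(sliceName = "character", nTopics = "integer",
                 contextTopic = "matrix", topicTarget = "matrix",
                 topicPrior = "numeric", trainingConfig = "list"),
  validity = function(object) {
    msg <- character()
    K <- object@nTopics
    if (K < 1L) msg <- c(msg, "nTopics must be >= 1")
    if (ncol(object@contextTopic) != K || nrow(object@topicTarget) != K ||
        length(object@topicPrior) != K)
      msg <- c(msg, "topic dimension mismatch across slots")
    m <- .checkSimplexRows(object@contextTopic, "contextTopic")
    if (!is.null(m)) msg <- c(msg, m)
    m <- .checkSimplexRows(object@topicTarget, "topicTarget")
    if (!is.null(m)) msg <- c(msg, m)
    if (any(object@topicPrior <= 0))
      msg <- c(msg, "topicPrior must be strictly positive")
    if (abs(sum(object@topicPrior) - 1) > .SIMPLEX_TOL)
      msg <- c(msg, "topicPrior must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' TopicDistribution: one word's distribution over topics
#'
#' @slot word word identifier.
#' @slot probs simplex vector over topics.
#' @slot source which matrix/rule produced it (\code{"context"} for a
#'   context-topic row, \code{"target"} for the Bayes-inverted target axis).
#' @seealso \code{\link{wordTopicDistribution}}
#' @export
setClass("TopicDistribution",
  representation(word = "character", probs = "numeric", source = "character"),
  validity = function(object) {
    p <- object@probs
    if (any(p < -.SIMPLEX_TOL)) return("probs must be non-negative")
    if (abs(sum(p) - 1) > .SIMPLEX_TOL) return("probs must sum to 1")
    TRUE
  })

#' CompletionSet: tallied sentence-completion responses for one stimulus
#'
#' @slot stimulusId stimulus identifier.
#' @slot stage \code{"SNP"} (continuations after the subject noun phrase) or
#'   \code{"SNP_VERB"} (continuations after subject noun phrase + verb,
#'   filtered to object nouns).
#' @slot responses named numeric vector of per-word response counts (>= 1).
#' @slot nTotal total surviving response count.
#' @slot included \code{TRUE} iff \code{nTotal >= 4}; stimuli with fewer
#'   responses are excluded from all downstream metrics.
#' @seealso \code{\link{tallyResponses}},
#'   \code{\link{completionDistribution}}
#' @export
setClass("CompletionSet",
  representation(stimulusId = "character", stage = "character",
                 responses = "numeric", nTotal = "numeric",
                 included = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@stage %in% c("SNP", "SNP_VERB"))
      msg <- c(msg, "stage must be 'SNP' or 'SNP_VERB'")
    if (length(object@responses)) {
      if (is.null(names(object@responses)))
        msg <- c(msg, "responses must be named by word")
      if (any(object@responses < 1)) msg <- c(msg, "counts must be >= 1")
    }
    if (object@nTotal != sum(object@responses))
      msg <- c(msg, "nTotal must equal the sum of counts")
    if (!identical(object@included, unname(object@nTotal >= 4)))
      msg <- c(msg, "included must be (nTotal >= 4)")
    if (length(msg)) msg else TRUE
  })

#' Blend: predicted-semantics distribution over topics for one stimulus
#'
#' The probability-weighted mixture of the topic distributions of the words
#' produced as continuations of a context, modeling P(topic | context).
#'
#' @slot stimulusId stimulus identifier.
#' @slot modelName which blend, e.g. \code{"SNP_to_verbs"},
#'   \code{"SNP_to_CNs"} or \code{"SNPverb_to_CNs"}.
#' @slot probs simplex vector over topics.
#' @slot contributingWords named numeric vector of the effective
#'   (renormalized) word weights after out-of-vocabulary dropping.
#' @seealso \code{\link{makeBlend}}
#' @export
setClass("Blend",
  representation(stimulusId = "character", modelName = "character",
                 probs = "numeric", contributingWords = "numeric"),
  validity = function(object) {
    p <- object@probs
    if (any(p < -.SIMPLEX_TOL)) return("probs must be non-negative")
    if (abs(sum(p) - 1) > .SIMPLEX_TOL) return("probs must sum to 1")
    TRUE
  })

#' DispersionWeights: within-topic semantic dispersion per topic
#'
#' For each topic, the mean pairwise cosine distance between the topic
#' distributions of the words that topic prefers. Used as per-topic weights
#' in \code{\link{weightedEntropy}}.
#'
#' @slot modelSlice slice of the topic model the weights were derived from.
#' @slot w numeric vector of dispersion weights, one per topic, each in
#'   [0, 2] (in [0, 1] for non-negative topic vectors).
#' @slot topK number of preferred words considered per topic.
#' @seealso \code{\link{topicDispersion}}
#' @export
setClass("DispersionWeights",
  representation(modelSlice = "character", w = "numeric", topK = "integer"),
  validity = function(object) {
    if (any(object@w < 0)) return("dispersion weights must be non-negative")
    if (object@topK < 2L) return("topK must be >= 2")
    TRUE
  })

#' CorticalMesh: source-space geometry
#'
#' Vertex coordinates (mm, shared template space) plus an undirected
#' adjacency used for cluster contiguity.
#'
#' @slot coords n_vertices x 3 numeric matrix of coordinates in mm.
#' @slot edges m x 2 integer matrix of undirected vertex index pairs
#'   (1-based, no self-edges; each pair stored once).
#' @export
setClass("CorticalMesh",
  representation(coords = "matrix", edges = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 3) msg <- c(msg, "coords must be n x 3")
    if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
    e <- object@edges
    if (nrow(e)) {
      if (ncol(e) != 2) msg <- c(msg, "edges must be m x 2")
      else {
        if (any(e < 1) || any(e > nrow(object@coords)))
          msg <- c(msg, "edge index out of range")
        if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-edges not allowed")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' SourceEpochs: one subject's source-space epoched data
#'
#' @slot subjectId subject identifier.
#' @slot data trials x vertices x time numeric array of source amplitudes
#'   (arbitrary units).
#' @slot timeMs per-sample latency in ms relative to the alignment point;
#'   uniformly spaced within [0, 600].
#' @slot epochName alignment point: \code{"SN_onset"}, \code{"verb_onset"}
#'   or \code{"CN_onset"}.
#' @slot trialIds unique stimulus ids, aligned to the first array dimension.
#' @export
setClass("SourceEpochs",
  representation(subjectId = "character", data = "array",
                 timeMs = "numeric", epochName = "character",
                 trialIds = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3) msg <- c(msg, "data must be trials x vertices x time")
    else {
      if (d[1] != length(object@trialIds))
        msg <- c(msg, "trialIds must match the trial dimension")
      if (d[3] != length(object@timeMs))
        msg <- c(msg, "timeMs must match the time dimension")
    }
    if (anyDuplicated(object@trialIds)) msg <- c(msg, "trialIds must be unique")
    tm <- object@timeMs
    if (length(tm) > 1) {
      dt <- diff(tm)
      if (any(abs(dt - dt[1]) > 1e-9))
        msg <- c(msg, "time axis must be uniformly sampled")
      if (min(tm) < -1e-9 || max(tm) > 600 + 1e-9)
        msg <- c(msg, "time axis must lie within [0, 600] ms")
    }
    if (!object@epochName %in% c("SN_onset", "verb_onset", "CN_onset"))
      msg <- c(msg, "unknown epochName")
    if (length(msg)) msg else TRUE
  })

#' RDM: representational dissimilarity matrix
#'
#' @slot labels trial/stimulus ids for rows and columns.
#' @slot d symmetric, zero-diagonal dissimilarity matrix. Data RDMs
#'   (1 - Pearson) lie in [0, 2]; model and covariate RDMs are absolute
#'   metric differences (or 0/1 for grouping covariates).
#' @slot kind \code{"model"}, \code{"data"} or \code{"covariate"}.
#' @export
setClass("RDM",
  representation(labels = "character", d = "matrix", kind = "character"),
  validity = function(object) {
    msg <- character()
    d <- object@d
    if (nrow(d) != ncol(d)) msg <- c(msg, "d must be square")
    if (nrow(d) != length(object@labels))
      msg <- c(msg, "labels must match the matrix dimension")
    if (max(abs(d - t(d))) > 1e-9) msg <- c(msg, "d must be symmetric")
    if (max(abs(diag(d))) > 1e-9) msg <- c(msg, "d must have a zero diagonal")
    if (!object@kind %in% c("model", "data", "covariate"))
      msg <- c(msg, "kind must be model, data or covariate")
    if (object@kind == "data" && (min(d) < -1e-8 || max(d) > 2 + 1e-8))
      msg <- c(msg, "data RDM entries must lie in [0, 2]")
    if (length(msg)) msg else TRUE
  })

#' SearchlightIndex: searchlight membership over a mesh and time axis
#'
#' Stored compactly: the spatial members of each vertex's 10 mm ball plus
#' the temporal half-width in samples; the members of center (v, t) are the
#' cross product of the two, truncated at the epoch edges (no wraparound).
#'
#' @slot spatialMembers list, per vertex, of member vertex indices within
#'   the spatial radius (always includes the vertex itself).
#' @slot halfwin temporal radius in samples.
#' @slot timeMs the epoch's time axis in ms.
#' @slot rMm,rMs the radii the index was built with (mm / ms).
#' @seealso \code{\link{buildSearchlightIndex}},
#'   \code{\link{searchlightMembers}}
#' @export
setClass("SearchlightIndex",
  representation(spatialMembers = "list", halfwin = "integer",
                 timeMs = "numeric", rMm = "numeric", rMs = "numeric"),
  validity = function(object) {
    ok <- vapply(seq_along(object@spatialMembers),
                 function(v) v %in% object@spatialMembers[[v]], logical(1))
    if (!all(ok)) return("every searchlight must contain its own center")
    if (object@halfwin < 0L) return("halfwin must be >= 0")
    TRUE
  })

#' SearchlightMap: per-subject searchlight model-fit maps
#'
#' @slot modelName model the maps were fit for.
#' @slot fits subjects x vertices x time array of partial Spearman fits in
#'   [-1, 1].
#' @slot subjectIds subject identifiers along the first dimension.
#' @slot timeMs epoch time axis along the third dimension.
#' @seealso \code{\link{subjectFitMaps}}, \code{\link{groupTMap}}
#' @export
setClass("SearchlightMap",
  representation(modelName = "character", fits = "array",
                 subjectIds = "character", timeMs = "numeric"),
  validity = function(object) {
    d <- dim(object@fits)
    if (length(d) != 3) return("fits must be subjects x vertices x time")
    if (d[1] != length(object@subjectIds))
      return("subjectIds must match the subject dimension")
    f <- object@fits[is.finite(object@fits)]
    if (length(f) && (min(f) < -1 - 1e-9 || max(f) > 1 + 1e-9))
      return("fit values must lie in [-1, 1]")
    TRUE
  })

#' TMap: group-level one-sample t statistic map
#'
#' @slot t vertices x time matrix of one-sample t values (NA where the
#'   across-subject variance is zero).
#' @slot df degrees of freedom (n_subjects - 1).
#' @slot tail \code{"positive"}: the test is one-sided for positive fits.
#' @export
setClass("TMap",
  representation(t = "matrix", df = "integer", tail = "character"),
  validity = function(object) {
    if (object@df < 1L) return("df must be >= 1")
    if (!object@tail %in% c("positive", "negative"))
      return("tail must be 'positive' or 'negative'")
    TRUE
  })

#' ClusterResult: supra-threshold clusters with permutation p-values
#'
#' @slot clusters list of clusters; each has \code{members} (2-column matrix
#'   of vertex index, time-sample index), \code{mass} (summed t) and
#'   \code{p} (sign-flip permutation p, add-one corrected).
#' @slot cftP cluster-forming threshold as a point-wise one-tailed p.
#' @slot tThreshold the Student-t quantile implementing \code{cftP}.
#' @slot nPerm number of sign-flip permutations.
#' @slot nullMaxMasses the permutation null of maximum cluster masses.
#' @slot seed RNG seed used for the permutations.
#' @slot df t-test degrees of freedom.
#' @slot timeMs epoch time axis (for reporting cluster onsets in ms).
#' @seealso \code{\link{signFlipPermutation}}, \code{\link{reportClusters}}
#' @export
setClass("ClusterResult",
  representation(clusters = "list", cftP = "numeric", tThreshold = "numeric",
                 nPerm = "integer", nullMaxMasses = "numeric",
                 seed = "integer", df = "integer", timeMs = "numeric"),
  validity = function(object) {
    if (length(object@nullMaxMasses) != object@nPerm)
      return("null must contain one maximum mass per permutation")
    for (cl in object@clusters) {
      if (cl$mass <= 0) return("cluster mass must be positive")
      if (cl$p <= 0 || cl$p > 1) return("cluster p must lie in (0, 1]")
    }
    TRUE
  })
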