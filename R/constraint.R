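#' Semantic blend of predicted words
#'
#' Computes \eqn{blend(words) = P(topic | context) = \sum_{word}
#' P(topic | word) P(word | context)}: the completion-probability-weighted
#' mixture of the topic distributions of the words participants produced as
#' continuations. Three blends are used in practice: predicted-verb
#' semantics given the subject noun phrase (SNP), predicted
#' complement-noun (CN) semantics given the SNP via the predicted verbs,
#' and predicted CN semantics given SNP + verb.
#'
#' Words missing from the topic lookup are dropped and the remaining
#' weights renormalized, so the result stays on the simplex;
#' \code{contributingWords} records the effective weights.
#'
#' @param weights named numeric vector of completion probabilities
#'   \eqn{P(word | context)} (from \code{\link{completionDistribution}}).
#' @param topicLookup words-by-topics matrix of topic distributions with
#'   word row names (see \code{\link{topicDistributionMatrix}}).
#' @param modelName blend identifier, e.g. \code{"SNP_to_verbs"}.
#' @param stimulusId stimulus the blend belongs to.
#' @return a \code{\linkS4class{Blend}}
#' @examples
#' lk <- rbind(A = c(0.8, 0.2), B = c(0.4, 0.6))
#' probs(makeBlend(c(A = 0.75, B = 0.25), lk, "SNP_to_verbs", "s1"))
#' @export
makeBlend <- function(weights, topicLookup, modelName, stimulusId = "") {
  stopifnot(is.matrix(topicLookup), !is.null(rownames(topicLookup)))
  words <- tolower(names(weights))
  known <- words %in% rownames(topicLookup)
  if (!any(known)) stop("no resolvable candidates")
  w <- as.numeric(weights[known])
  w <- w / sum(w)
  names(w) <- words[known]
  p <- as.numeric(w %*% topicLookup[words[known], , drop = FALSE])
  s <- sum(p)
  if (s <= 0) stop("blend collapsed to a zero vector")
  new("Blend", stimulusId = stimulusId, modelName = modelName,
      probs = p / s, contributingWords = w)
}

#' Within-topic semantic dispersion weights
#'
#' For each topic, takes the \code{topK} target words with the highest
#' \eqn{P(word | topic)}, fetches each word's own (target-axis) topic
#' distribution, and averages 1 minus cosine similarity over all unordered
#' word pairs. If a topic's preferred words have similar distributions the
#' dispersion is low; a topic preferring semantically scattered words gets
#' a high weight. The weights feed \code{\link{weightedEntropy}} so that
#' within-topic dispersion is controlled when computing between-topic
#' constraint strength.
#'
#' @param model a \code{\linkS4class{TopicModel}}
#' @param topK number of preferred words per topic (default 20).
#' @param invert if \code{TRUE}, use \code{max(w) - w} instead, making
#'   dispersed topics count less rather than more. The default follows the
#'   dispersion-weight formula as written.
#' @return a \code{\linkS4class{DispersionWeights}}
#' @export
topicDispersion <- function(model, topK = 20, invert = FALSE) {
  stopifnot(is(model, "TopicModel"))
  topK <- as.integer(topK)
  if (topK < 2L) stop("topK must be >= 2")
  K <- model@nTopics
  tt <- model@topicTarget
  ## target-axis distributions for the whole vocabulary, by Bayes inversion
  post <- tt * model@topicPrior          # K x V, column j ~ P(topic | word j)
  cs <- colSums(post)
  w <- numeric(K)
  degenerate <- 0L
  for (k in seq_len(K)) {
    nz <- which(tt[k, ] > 0 & cs > 0)
    if (length(nz) < 2L) {
      degenerate <- degenerate + 1L
      next
    }
    top <- nz[order(tt[k, nz], decreasing = TRUE)][seq_len(min(topK, length(nz)))]
    D <- sweep(post[, top, drop = FALSE], 2, cs[top], "/")  # K x m columns
    nrm <- sqrt(colSums(D^2))
    C <- crossprod(D) / outer(nrm, nrm)
    w[k] <- mean(1 - C[upper.tri(C)])
  }
  if (degenerate)
    warning(sprintf("%d topic(s) had fewer than 2 nonzero-probability words; dispersion set to 0",
                    degenerate))
  w <- pmax(w, 0)
  if (invert) w <- max(w) - w
  new("DispersionWeights", modelSlice = model@sliceName, w = w, topK = topK)
}

#' Dispersion-corrected entropy of a blend
#'
#' \eqn{H(P) = \sum_i w_i [-P_i \log P_i]} in nats, with
#' \eqn{0 \log 0 = 0}. With unit weights this is Shannon entropy; with
#' \code{\link{topicDispersion}} weights each topic's local entropy
#' contribution is scaled by that topic's within-topic semantic
#' dispersion. Natural log is used throughout: a different base rescales
#' every trial identically, leaving absolute-difference model RDMs
#' proportional and rank-based model fits unchanged.
#'
#' @param p a \code{\linkS4class{Blend}} or simplex numeric vector.
#' @param w a \code{\linkS4class{DispersionWeights}} or numeric vector of
#'   the same length as \code{p}.
#' @return entropy in nats (>= 0 for non-negative weights)
#' @examples
#' weightedEntropy(rep(0.01, 100), rep(1, 100))  # ln(100)
#' @export
weightedEntropy <- function(p, w) {
  if (is(p, "Blend")) p <- p@probs
  if (is(w, "DispersionWeights")) w <- w@w
  if (length(p) != length(w))
    stop(sprintf("length mismatch: %d probabilities vs %d weights",
                 length(p), length(w)))
  h <- numeric(length(p))
  pos <- p > 0
  h[pos] <- -p[pos] * log(p[pos])
  sum(w * h)
}

#' Cosine mismatch between predicted and target semantics
#'
#' \eqn{1 - a \cdot b / (\|a\| \|b\|)}: the cosine distance between the
#' blend of predicted complement nouns and the topic distribution of the
#' noun actually heard. Lies in [0, 1] for non-negative vectors (in
#' [0, 2] generally); 0 means the prediction matches the target exactly.
#'
#' @param target a \code{\linkS4class{TopicDistribution}} (or numeric
#'   vector): topic distribution of the heard word.
#' @param predicted a \code{\linkS4class{Blend}} (or numeric vector) of the
#'   same length.
#' @return cosine distance
#' @examples
#' cosineMismatch(c(1, 0), c(0.5, 0.5))  # 1 - 1/sqrt(2)
#' @export
cosineMismatch <- function(target, predicted) {
  if (is(target, "TopicDistribution")) target <- target@probs
  if (is(predicted, "Blend")) predicted <- predicted@probs
  if (length(target) != length(predicted))
    stop("target and predicted vectors must have equal length")
  na <- sqrt(sum(target^2))
  nb <- sqrt(sum(predicted^2))
  if (na == 0 || nb == 0) stop("cosine distance undefined for a zero vector")
  1 - sum(target * predicted) / (na * nb)
}

#' Build a per-stimulus constraint metric table
#'
#' Evaluates one scalar per stimulus for one model: dispersion-corrected
#' entropy of the stimulus's blend (\code{metricKind = "entropy"}) or
#' cosine mismatch between the blend and the target word's topic
#' distribution (\code{metricKind = "mismatch"}). Mismatch rows are
#' restricted to stimuli whose heard complement word is an identified
#' complement noun (an object of the verb), since the mismatch model needs
#' the target CN; stimuli without one are skipped silently. Stimuli with a
#' missing blend are dropped with a warning.
#'
#' @param stimuli stimulus metadata data frame with columns
#'   \code{stimulus_id} and, for mismatch, logical \code{has_cn}.
#' @param blends named list of \code{\linkS4class{Blend}} keyed by
#'   stimulus id.
#' @param metricKind \code{"entropy"} or \code{"mismatch"}.
#' @param modelName name recorded in the table (defaults to the blends'
#'   model name).
#' @param dispersion \code{\linkS4class{DispersionWeights}} or numeric
#'   weight vector for entropy; unit weights if omitted.
#' @param targetDists for mismatch: named list (by stimulus id) of
#'   \code{\linkS4class{TopicDistribution}} for each stimulus's target CN.
#' @return data frame `stimulus_id  model_name  metric_kind  value`
#' @export
buildMetricTable <- function(stimuli, blends,
                             metricKind = c("entropy", "mismatch"),
                             modelName = NULL, dispersion = NULL,
                             targetDists = NULL) {
  metricKind <- match.arg(metricKind)
  ids <- as.character(stimuli$stimulus_id)
  if (metricKind == "mismatch") {
    if (is.null(stimuli$has_cn))
      stop("mismatch metric needs a 'has_cn' column in the stimulus table")
    ids <- ids[stimuli$has_cn]
    if (is.null(targetDists))
      stop("mismatch metric needs targetDists (topic distribution of each target CN)")
  }
  missing <- setdiff(ids, names(blends))
  if (length(missing)) {
    warning(sprintf("dropping %d stimulus(-i) with no blend: %s",
                    length(missing), paste(head(missing, 5), collapse = ", ")))
    ids <- setdiff(ids, missing)
  }
  if (!length(ids)) stop("no stimuli left for the metric table")
  if (is.null(modelName)) modelName <- blends[[ids[1]]]@modelName
  value <- vapply(ids, function(id) {
    b <- blends[[id]]
    if (metricKind == "entropy") {
      w <- if (is.null(dispersion)) rep(1, length(b@probs)) else dispersion
      weightedEntropy(b, w)
    } else {
      if (is.null(targetDists[[id]]))
        stop(sprintf("no target CN distribution for stimulus '%s'", id))
      cosineMismatch(targetDists[[id]], b)
    }
  }, numeric(1))
  data.frame(stimulus_id = ids, model_name = modelName,
             metric_kind = metricKind, value = as.numeric(value),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a constraint metric table
#'
#' TSV with columns `stimulus_id  model_name  metric_kind  value`.
#'
#' @param x metric table data frame.
#' @param path file path.
#' @return the path (write) or the data frame (read)
#' @export
writeMetricTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "model_name", "metric_kind", "value")
  if (!all(need %in% names(df)))
    stop("metric table must have columns: ", paste(need, collapse = ", "))
  df
}
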