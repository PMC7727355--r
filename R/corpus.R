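#' Construct a CooccurrenceTable
#'
#' @param counts non-negative numeric matrix of co-occurrence counts with
#'   context words as row names and target words as column names.
#' @param sliceName slice identifier (e.g. \code{"SN_V"}, \code{"SNV_CN"}).
#' @return a \code{\linkS4class{CooccurrenceTable}}
#' @examples
#' counts <- matrix(c(10, 0, 0, 10), 2, 2,
#'                  dimnames = list(c("walker", "court"), c("chose", "denied")))
#' cooccurrenceTable(counts, "SN_V")
#' @export
cooccurrenceTable <- function(counts, sliceName) {
  storage.mode(counts) <- "double"
  new("CooccurrenceTable", sliceName = sliceName, counts = counts)
}

#' Read a co-occurrence slice from TSV
#'
#' Expects the long format `context_word  target_word  count` with a header
#' row; duplicate (context, target) rows are summed.
#'
#' @param path TSV file path.
#' @param sliceName slice identifier stored on the result.
#' @return a \code{\linkS4class{CooccurrenceTable}}
#' @export
readCooccurrenceTSV <- function(path, sliceName) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("context_word", "target_word", "count")
  if (!all(need %in% names(df)))
    stop("co-occurrence TSV must have columns: ", paste(need, collapse = ", "))
  ctx <- sort(unique(df$context_word))
  tgt <- sort(unique(df$target_word))
  m <- matrix(0, length(ctx), length(tgt), dimnames = list(ctx, tgt))
  idx <- cbind(match(df$context_word, ctx), match(df$target_word, tgt))
  for (i in seq_len(nrow(df))) m[idx[i, 1], idx[i, 2]] <-
      m[idx[i, 1], idx[i, 2]] + df$count[i]
  cooccurrenceTable(m, sliceName)
}

#' Local mutual information weighting of a co-occurrence table
#'
#' Fills the \code{weighted} slot with
#' \eqn{w_{ct} = n_{ct} \log( n_{ct} N / (r_c s_t) )}, where \eqn{N} is the
#' grand total and \eqn{r_c, s_t} the row/column sums. LMI normalizes away
#' the lexical frequency of the individual items, so the weight reflects
#' association rather than raw frequency. Cells with zero counts, and cells
#' whose pointwise mutual information is negative, get weight 0, which
#' keeps the weights usable as (scaled) token counts for topic-model
#' training.
#'
#' @param x a \code{\linkS4class{CooccurrenceTable}}
#' @return the table with \code{weighted} filled
#' @examples
#' counts <- matrix(c(10, 0, 0, 10), 2, 2,
#'                  dimnames = list(c("c1", "c2"), c("t1", "t2")))
#' lmiWeights(computeLMI(cooccurrenceTable(counts, "SN_V")))
#' @export
computeLMI <- function(x) {
  stopifnot(is(x, "CooccurrenceTable"))
  n <- x@counts
  N <- sum(n)
  if (N <= 0) stop("empty co-occurrence table")
  rs <- rowSums(n)
  cs <- colSums(n)
  expected <- outer(rs, cs) / N
  w <- matrix(0, nrow(n), ncol(n), dimnames = dimnames(n))
  pos <- n > 0
  w[pos] <- n[pos] * log(n[pos] / expected[pos])
  w[w < 0] <- 0
  x@weighted <- w
  validObject(x)
  x
}

#' Train an LDA topic model on an LMI-weighted co-occurrence slice
#'
#' Each context word is treated as one "document" whose token multiset is
#' its target words replicated proportionally to the rounded, scaled LMI
#' weight. A collapsed Gibbs sampler (seeded, bitwise reproducible) then
#' estimates the posterior expectations of the document-topic and
#' topic-word multinomials; \code{contextTopic} and \code{topicTarget} are
#' the smoothed posterior means, and \code{topicPrior} is the normalized
#' expected topic count over all documents (Dirichlet-smoothed, so it is
#' strictly positive).
#'
#' @param x a weighted \code{\linkS4class{CooccurrenceTable}} (run
#'   \code{\link{computeLMI}} first).
#' @param nTopics number of topics (the study default is 100).
#' @param alpha document-topic Dirichlet hyperparameter; default
#'   \code{50 / nTopics}.
#' @param beta topic-word Dirichlet hyperparameter; default 0.01.
#' @param nIter Gibbs sweeps; default 1000.
#' @param seed RNG seed; identical configuration and seed give bitwise
#'   identical models.
#' @param weightScale LMI weights are multiplied by this factor and rounded
#'   to integer token counts (default 10), preserving relative weighting
#'   while meeting the count assumption of the sampler.
#' @return a \code{\linkS4class{TopicModel}}
#' @export
trainTopicModel <- function(x, nTopics = 100, alpha = 50 / nTopics,
                            beta = 0.01, nIter = 1000, seed = 1,
                            weightScale = 10) {
  stopifnot(is(x, "CooccurrenceTable"))
  if (is.null(x@weighted))
    stop("co-occurrence table has no LMI weights; run computeLMI() first")
  nTopics <- as.integer(nTopics)
  if (nTopics < 1L) stop("nTopics must be >= 1")
  if (nTopics > ncol(x@counts))
    stop(sprintf("nTopics (%d) exceeds the number of distinct targets (%d)",
                 nTopics, ncol(x@counts)))
  tok <- round(x@weighted * weightScale)
  keep <- rowSums(tok) > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d context word(s) with all-zero weights: %s",
                    sum(!keep),
                    paste(head(rownames(tok)[!keep], 5), collapse = ", ")))
    tok <- tok[keep, , drop = FALSE]
  }
  if (!nrow(tok)) stop("no context words left after zero-weight exclusion")
  contexts <- rownames(tok)
  targets <- colnames(tok)
  nz <- which(tok > 0, arr.ind = TRUE)
  reps <- tok[nz]
  doc <- rep.int(nz[, 1] - 1L, reps)
  word <- rep.int(nz[, 2] - 1L, reps)

  fit <- lda_gibbs_cpp(as.integer(doc), as.integer(word),
                       n_docs = length(contexts), n_words = length(targets),
                       n_topics = nTopics, alpha = alpha, beta = beta,
                       n_iter = as.integer(nIter),
                       seed = as.integer(seed) %% .Machine$integer.max)
  ndk <- fit$ndk
  nkw <- fit$nkw
  ct <- (ndk + alpha) / (rowSums(ndk) + nTopics * alpha)
  tt <- (nkw + beta) / (rowSums(nkw) + length(targets) * beta)
  prior <- (fit$nk + alpha) / (sum(fit$nk) + nTopics * alpha)
  dimnames(ct) <- list(contexts, NULL)
  dimnames(tt) <- list(NULL, targets)
  new("TopicModel", sliceName = x@sliceName, nTopics = nTopics,
      contextTopic = ct, topicTarget = tt, topicPrior = as.numeric(prior),
      trainingConfig = list(method = "collapsed_gibbs", alpha = alpha,
                            beta = beta, nIter = nIter, seed = seed,
                            weightScale = weightScale))
}

#' Topic distribution of a single word
#'
#' For \code{axis = "context"} the word's row of the document-topic matrix
#' is returned directly. For \code{axis = "target"} the topic-word matrix
#' is Bayes-inverted: \eqn{P(topic|word) \propto P(word|topic) P(topic)},
#' renormalized. A word present in both vocabularies can legitimately have
#' different distributions on the two axes; there is no cross-axis
#' fallback.
#'
#' @param model a \code{\linkS4class{TopicModel}}
#' @param word word identifier (case-folded exact match).
#' @param axis \code{"context"} or \code{"target"}.
#' @return a \code{\linkS4class{TopicDistribution}}
#' @export
wordTopicDistribution <- function(model, word, axis = c("context", "target")) {
  stopifnot(is(model, "TopicModel"))
  axis <- match.arg(axis)
  word <- tolower(word)
  if (axis == "context") {
    i <- match(word, rownames(model@contextTopic))
    if (is.na(i))
      stop(sprintf("word '%s' not in the context vocabulary", word))
    p <- model@contextTopic[i, ]
  } else {
    j <- match(word, colnames(model@topicTarget))
    if (is.na(j))
      stop(sprintf("word '%s' not in the target vocabulary", word))
    p <- model@topicTarget[, j] * model@topicPrior
    s <- sum(p)
    if (s <= 0) stop(sprintf("word '%s' has zero posterior mass", word))
    p <- p / s
  }
  new("TopicDistribution", word = word, probs = as.numeric(p), source = axis)
}

#' Topic distributions for a set of words, as a matrix
#'
#' Convenience wrapper around \code{\link{wordTopicDistribution}} returning
#' a words-by-topics matrix suitable for \code{\link{makeBlend}}.
#'
#' @inheritParams wordTopicDistribution
#' @param words character vector of word identifiers.
#' @return numeric matrix, one simplex row per word.
#' @export
topicDistributionMatrix <- function(model, words, axis = c("context", "target")) {
  axis <- match.arg(axis)
  m <- t(vapply(words,
                function(w) wordTopicDistribution(model, w, axis)@probs,
                numeric(model@nTopics)))
  rownames(m) <- tolower(words)
  m
}
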