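#' Tally raw sentence-completion responses into per-stimulus sets
#'
#' Aggregates a raw response table into one \code{CompletionSet} per
#' stimulus. For the second-stage study (\code{stage = "SNP_VERB"},
#' continuations after subject noun phrase + verb) only responses flagged
#' as object nouns of the preceding verb are kept, because nouns inside
#' e.g. a sentential complement act as new subjects rather than objects.
#' A stimulus whose surviving responses number fewer than 4 is marked
#' \code{included = FALSE} and is excluded from all downstream metrics;
#' the threshold is applied after the object-role filter.
#'
#' @param raw data frame with columns \code{stimulus_id},
#'   \code{response_word}, optionally \code{count} (default 1 per row) and,
#'   for \code{stage = "SNP_VERB"}, optionally \code{is_object} (logical).
#'   Duplicate (stimulus, word) rows are summed, not rejected. Responses
#'   are expected to be single head words, extracted upstream.
#' @param stage \code{"SNP"} or \code{"SNP_VERB"}.
#' @param validWords optional character vector; responses outside it are
#'   dropped before tallying.
#' @return named list of \code{\linkS4class{CompletionSet}}, one per
#'   stimulus id present in \code{raw} (stimuli whose responses are all
#'   filtered away are kept, with zero counts and \code{included = FALSE}).
#' @export
tallyResponses <- function(raw, stage = c("SNP", "SNP_VERB"),
                           validWords = NULL) {
  stage <- match.arg(stage)
  if (!nrow(raw)) {
    warning("empty response table")
    return(list())
  }
  need <- c("stimulus_id", "response_word")
  if (!all(need %in% names(raw)))
    stop("response table must have columns: ", paste(need, collapse = ", "))
  if (is.null(raw$count)) raw$count <- 1L
  if (any(raw$count < 0)) stop("negative response counts")
  raw$response_word <- tolower(raw$response_word)
  ids <- unique(as.character(raw$stimulus_id))

  keep <- rep(TRUE, nrow(raw))
  if (stage == "SNP_VERB" && !is.null(raw$is_object))
    keep <- keep & as.logical(raw$is_object)
  if (!is.null(validWords))
    keep <- keep & raw$response_word %in% tolower(validWords)
  kept <- raw[keep & raw$count > 0, , drop = FALSE]

  out <- lapply(ids, function(id) {
    rows <- kept[as.character(kept$stimulus_id) == id, , drop = FALSE]
    counts <- if (nrow(rows)) {
      v <- tapply(rows$count, rows$response_word, sum)
      setNames(as.numeric(v), names(v))
    } else numeric()
    n <- sum(counts)
    new("CompletionSet", stimulusId = id, stage = stage,
        responses = counts, nTotal = n, included = unname(n >= 4))
  })
  names(out) <- ids
  out
}

#' Conditional word distribution of a completion set
#'
#' Normalizes the tallied counts into \eqn{P(word | context)}: each count
#' divided by the total, renormalized so the result sums to 1 exactly.
#'
#' @param cs an included \code{\linkS4class{CompletionSet}}
#' @return named numeric vector of probabilities summing to 1
#' @examples
#' cs <- new("CompletionSet", stimulusId = "s1", stage = "SNP",
#'           responses = c(path = 3, route = 1), nTotal = 4, included = TRUE)
#' completionDistribution(cs)  # path 0.75, route 0.25
#' @export
completionDistribution <- function(cs) {
  stopifnot(is(cs, "CompletionSet"))
  if (!cs@included) stop("stimulus excluded (<4 responses)")
  p <- cs@responses / cs@nTotal
  p / sum(p)
}

#' Read a raw completion-response TSV
#'
#' Long format `stimulus_id  stage  response_word  count  is_object`
#' (\code{is_object} is ignored for first-stage rows).
#'
#' @param path TSV file path.
#' @return data frame with the stage column retained; pass the relevant
#'   subset to \code{\link{tallyResponses}}.
#' @export
readCompletionsTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "stage", "response_word")
  if (!all(need %in% names(df)))
    stop("completions TSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.na(df$count) & df$count < 0))
    stop("negative count in completions TSV")
  df
}

#' Write per-stimulus completion distributions to TSV
#'
#' Columns: `stimulus_id  stage  word  prob  n_total  included`. Excluded
#' stimuli are written with no word rows beyond a single NA marker row so
#' the exclusion is visible in the file.
#'
#' @param sets list of \code{\linkS4class{CompletionSet}} from
#'   \code{\link{tallyResponses}}.
#' @param path output TSV path.
#' @return the path, invisibly
#' @export
writeCompletionDistributions <- function(sets, path) {
  rows <- lapply(sets, function(cs) {
    if (cs@included) {
      p <- completionDistribution(cs)
      data.frame(stimulus_id = cs@stimulusId, stage = cs@stage,
                 word = names(p), prob = as.numeric(p),
                 n_total = cs@nTotal, included = TRUE)
    } else {
      data.frame(stimulus_id = cs@stimulusId, stage = cs@stage,
                 word = NA_character_, prob = NA_real_,
                 n_total = cs@nTotal, included = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
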