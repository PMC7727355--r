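#' Construct a cortical mesh
#'
#' @param coords n_vertices x 3 matrix of coordinates in mm (one shared
#'   template space for all subjects).
#' @param edges m x 2 matrix of undirected vertex index pairs used for
#'   cluster contiguity. Duplicates and reversed pairs are collapsed.
#' @return a \code{\linkS4class{CorticalMesh}}
#' @export
corticalMesh <- function(coords, edges) {
  coords <- as.matrix(coords)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  new("CorticalMesh", coords = coords, edges = edges)
}

#' Per-vertex neighbor list from mesh edges (includes the vertex itself)
#' @param mesh a \code{\linkS4class{CorticalMesh}}
#' @return list of integer vectors
#' @keywords internal
meshNeighborList <- function(mesh) {
  n <- nrow(mesh@coords)
  nb <- vector("list", n)
  for (v in seq_len(n)) nb[[v]] <- integer()
  e <- mesh@edges
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
    nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
  }
  lapply(nb, function(x) sort(unique(x)))
}

#' Model RDM from per-stimulus metric values
#'
#' The representational geometry of a scalar summary metric:
#' \eqn{d_{ij} = |v_i - v_j|} for every pair of trials.
#'
#' @param metrics a metric table from \code{\link{buildMetricTable}}, or a
#'   named numeric vector of per-stimulus values.
#' @return an \code{\linkS4class{RDM}} of kind \code{"model"}
#' @export
modelRDM <- function(metrics) {
  if (is.data.frame(metrics)) {
    v <- setNames(metrics$value, as.character(metrics$stimulus_id))
  } else v <- metrics
  if (length(v) < 3) stop("model RDM needs at least 3 stimuli")
  if (is.null(names(v))) names(v) <- paste0("trial", seq_along(v))
  if (sd(v) == 0) stop("degenerate model RDM (zero variance)")
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- NULL
  new("RDM", labels = names(v), d = d, kind = "model")
}

#' Nuisance covariate RDMs for one epoch
#'
#' Two covariates are partialled out of every searchlight model fit:
#' \enumerate{
#'   \item lexical frequency of the word the epoch is aligned to
#'     (absolute difference of log frequency);
#'   \item repetition of the SNP + verb combination across trials
#'     (0 when two trials share the same combination group, else 1).
#' }
#'
#' @param stimuli stimulus metadata with columns \code{stimulus_id},
#'   \code{rep_group}, and the epoch's log-frequency column
#'   (\code{sn_logfreq}, \code{verb_logfreq} or \code{cn_logfreq}).
#' @param epochName \code{"SN_onset"}, \code{"verb_onset"} or
#'   \code{"CN_onset"}.
#' @param labels optional subset/order of stimulus ids (defaults to all).
#' @return named list of two \code{\linkS4class{RDM}}s
#'   (\code{frequency}, \code{repetition})
#' @export
covariateRDMs <- function(stimuli, epochName, labels = NULL) {
  col <- switch(epochName,
                SN_onset = "sn_logfreq", verb_onset = "verb_logfreq",
                CN_onset = "cn_logfreq",
                stop("unknown epochName: ", epochName))
  if (is.null(stimuli[[col]]))
    stop(sprintf("epoch '%s' needs a '%s' column in the stimulus table",
                 epochName, col))
  if (is.null(stimuli$rep_group))
    stop(sprintf("epoch '%s' needs a 'rep_group' column in the stimulus table",
                 epochName))
  ids <- as.character(stimuli$stimulus_id)
  if (is.null(labels)) labels <- ids
  i <- match(labels, ids)
  if (anyNA(i)) stop("labels not found in the stimulus table")
  f <- stimuli[[col]][i]
  if (anyNA(f))
    stop(sprintf("missing values in '%s' for epoch '%s'", col, epochName))
  g <- as.character(stimuli$rep_group[i])
  freq <- abs(outer(f, f, "-"))
  rep_ <- 1 - outer(g, g, "==")
  diag(rep_) <- 0
  dimnames(freq) <- dimnames(rep_) <- NULL
  list(frequency = new("RDM", labels = labels, d = freq, kind = "covariate"),
       repetition = new("RDM", labels = labels, d = rep_ * 1.0,
                        kind = "covariate"))
}

#' Build the searchlight index for a mesh and time axis
#'
#' A (vertex, time) point belongs to the searchlight centered at (v, t)
#' iff its Euclidean distance from v is at most \code{rMm} and its latency
#' differs by at most \code{rMs}. Windows are truncated at the epoch edges
#' (no wraparound). Defaults are a 10 mm spatial and 30 ms temporal
#' radius.
#'
#' @param mesh a \code{\linkS4class{CorticalMesh}}
#' @param timeMs uniformly sampled epoch time axis in ms.
#' @param rMm spatial radius in mm (> 0).
#' @param rMs temporal radius in ms (> 0).
#' @return a \code{\linkS4class{SearchlightIndex}}
#' @export
buildSearchlightIndex <- function(mesh, timeMs, rMm = 10, rMs = 30) {
  stopifnot(is(mesh, "CorticalMesh"))
  if (rMm <= 0 || rMs <= 0) stop("searchlight radii must be positive")
  n <- nrow(mesh@coords)
  if (!n) stop("empty mesh")
  d <- as.matrix(dist(mesh@coords))
  members <- lapply(seq_len(n), function(v) which(d[v, ] <= rMm))
  dt <- if (length(timeMs) > 1) timeMs[2] - timeMs[1] else Inf
  halfwin <- if (is.finite(dt)) as.integer(floor(rMs / dt + 1e-9)) else 0L
  new("SearchlightIndex", spatialMembers = members, halfwin = halfwin,
      timeMs = timeMs, rMm = rMm, rMs = rMs)
}

#' Members of one searchlight center
#'
#' @param index a \code{\linkS4class{SearchlightIndex}}
#' @param vertex center vertex index.
#' @param timeIdx center time-sample index.
#' @return 2-column matrix (vertex, timeIdx) of member points
#' @export
searchlightMembers <- function(index, vertex, timeIdx) {
  sv <- index@spatialMembers[[vertex]]
  tt <- seq(max(1L, timeIdx - index@halfwin),
            min(length(index@timeMs), timeIdx + index@halfwin))
  cbind(vertex = rep(sv, each = length(tt)),
        timeIdx = rep(tt, times = length(sv)))
}

#' Data RDM for one searchlight
#'
#' Per trial, the amplitudes at the member (vertex, time) points are
#' flattened to one vector; the dissimilarity between two trials is
#' 1 minus the Pearson correlation of their vectors (range [0, 2]).
#' A trial whose member vector has zero variance has undefined
#' correlations; its pairs are set to the maximal "no shared pattern"
#' distance of 1, with a warning.
#'
#' @param epochs a \code{\linkS4class{SourceEpochs}} (>= 3 trials).
#' @param members 2-column matrix (vertex, timeIdx) from
#'   \code{\link{searchlightMembers}}; at least 2 member points.
#' @return an \code{\linkS4class{RDM}} of kind \code{"data"}
#' @export
dataRDM <- function(epochs, members) {
  stopifnot(is(epochs, "SourceEpochs"))
  if (nrow(members) < 2) stop("searchlight must have at least 2 member points")
  nT <- dim(epochs@data)[1]
  if (nT < 3) stop("data RDM needs at least 3 trials")
  v <- matrix(NA_real_, nT, nrow(members))
  for (j in seq_len(nrow(members)))
    v[, j] <- epochs@data[, members[j, 1], members[j, 2]]
  s <- apply(v, 1, sd)
  d <- matrix(1, nT, nT)
  ok <- s > 0
  if (any(!ok))
    warning(sprintf("%d trial vector(s) with zero variance; their distances set to 1",
                    sum(!ok)))
  if (sum(ok) >= 2)
    d[ok, ok] <- 1 - cor(t(v[ok, , drop = FALSE]))
  diag(d) <- 0
  d[d < 0] <- 0           # guard FP noise below 0
  d[d > 2] <- 2
  d <- (d + t(d)) / 2
  new("RDM", labels = epochs@trialIds, d = d, kind = "data")
}
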