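## Group-level searchlight statistics: partial Spearman model fits,
## one-sample t-maps, cluster forming and sign-flip permutation inference.

.alignRDM <- function(x, labels) {
  i <- match(labels, x@labels)
  if (anyNA(i)) stop("RDM label sets do not match")
  new("RDM", labels = labels, d = x@d[i, i, drop = FALSE], kind = x@kind)
}

#' Partial Spearman correlation between a data and a model RDM
#'
#' The column-wise lower triangles of all RDMs are rank-transformed (ties
#' get average ranks); the model and data ranks are each residualized on
#' the covariate ranks plus an intercept by least squares, and the fit is
#' the Pearson correlation of the two residual vectors. With no covariates
#' this is exactly classical Spearman's rho.
#'
#' @param data,model \code{\linkS4class{RDM}}s over the same label set
#'   (at least 3 labels). \code{model} (and covariates) are re-ordered to
#'   \code{data}'s labels.
#' @param covariates list of covariate \code{\linkS4class{RDM}}s to
#'   partial out (e.g. from \code{\link{covariateRDMs}}).
#' @return the fit in [-1, 1]; defined as 0 (with a warning) when either
#'   residual vector has no variance left, e.g. when a covariate is
#'   identical to the model.
#' @export
partialSpearman <- function(data, model, covariates = list()) {
  stopifnot(is(data, "RDM"), is(model, "RDM"))
  labels <- data@labels
  if (length(labels) < 3) stop("partial Spearman needs at least 3 labels")
  model <- .alignRDM(model, labels)
  covariates <- lapply(covariates, .alignRDM, labels = labels)
  dv <- rank(rdmVector(data))
  mv <- rank(rdmVector(model))
  n <- length(dv)
  if (n < length(covariates) + 2)
    stop("fewer RDM triangle entries than covariates + 2")
  X <- matrix(1, n, 1)
  for (cv in covariates) X <- cbind(X, rank(rdmVector(cv)))
  qrX <- qr(X)
  rd <- qr.resid(qrX, dv)
  rm_ <- qr.resid(qrX, mv)
  sm <- sqrt(sum(rm_^2))
  sdv <- sqrt(sum(rd^2))
  if (sm < 1e-10 || sdv < 1e-10) {
    warning("zero residual variance (covariate identical to model or data); fit set to 0")
    return(0)
  }
  sum(rd * rm_) / (sdv * sm)
}

#' Searchlight model-fit maps for a set of subjects
#'
#' For every searchlight center of every subject: compute the data RDM
#' (1 - Pearson over the center's member amplitudes), then the partial
#' Spearman fit against the model RDM with the covariate RDMs partialled
#' out. Centers are independent, so the result does not depend on
#' evaluation order. The heavy loop runs in compiled code;
#' \code{\link{partialSpearman}} + \code{\link{dataRDM}} give the same
#' value for any single center.
#'
#' The trials used per subject are the intersection of the model's labels
#' with the subject's trials; a subject missing more than half of the
#' model's trials is excluded with a warning.
#'
#' @param epochsList list of \code{\linkS4class{SourceEpochs}} (one per
#'   subject, shared mesh and time axis).
#' @param index \code{\linkS4class{SearchlightIndex}} for the shared mesh
#'   and time axis.
#' @param model model \code{\linkS4class{RDM}}.
#' @param covariates list of covariate \code{\linkS4class{RDM}}s.
#' @return a \code{\linkS4class{SearchlightMap}}
#' @export
subjectFitMaps <- function(epochsList, index, model, covariates = list()) {
  stopifnot(length(epochsList) >= 1, is(index, "SearchlightIndex"))
  labels <- model@labels
  nV <- length(index@spatialMembers)
  nT <- length(index@timeMs)
  keep <- character()
  mats <- list()
  for (ep in epochsList) {
    present <- intersect(labels, ep@trialIds)
    if (length(present) < length(labels) / 2) {
      warning(sprintf("subject %s missing more than 50%% of model trials; excluded",
                      ep@subjectId))
      next
    }
    msub <- .alignRDM(model, present)
    csub <- lapply(covariates, .alignRDM, labels = present)
    mv <- rank(rdmVector(msub))
    X <- matrix(1, length(mv), 1)
    for (cv in csub) X <- cbind(X, rank(rdmVector(cv)))
    Q <- qr.Q(qr(X))
    mres <- mv - Q %*% crossprod(Q, mv)
    nm <- sqrt(sum(mres^2))
    if (nm < 1e-10)
      stop("model RDM has no rank variance left after covariates")
    Xd <- ep@data[match(present, ep@trialIds), , , drop = FALSE]
    mats[[length(mats) + 1L]] <-
      sl_fit_map_cpp(Xd, index@spatialMembers, index@halfwin,
                     as.numeric(mres / nm), Q)
    keep <- c(keep, ep@subjectId)
  }
  if (!length(mats)) stop("no subjects left after trial-coverage exclusion")
  fits <- array(NA_real_, c(length(mats), nV, nT))
  for (s in seq_along(mats)) fits[s, , ] <- mats[[s]]
  new("SearchlightMap", modelName = "model", fits = fits,
      subjectIds = keep, timeMs = index@timeMs)
}

#' Group one-sample t-map over subject fit maps
#'
#' Per searchlight center, a one-sample t of the subject fit values
#' against 0 (one-tailed, positive direction: the model fit is predicted
#' positive). Centers with zero across-subject variance are undefined and
#' flagged NA (they count as sub-threshold downstream).
#'
#' @param maps a \code{\linkS4class{SearchlightMap}} with at least 3
#'   subjects.
#' @return a \code{\linkS4class{TMap}} with df = n_subjects - 1
#' @export
groupTMap <- function(maps) {
  stopifnot(is(maps, "SearchlightMap"))
  n <- dim(maps@fits)[1]
  if (n < 3) stop("group t-map needs at least 3 subjects")
  nV <- dim(maps@fits)[2]
  nT <- dim(maps@fits)[3]
  F <- matrix(maps@fits, nrow = n)          # columns in (vertex, time) order
  m <- colMeans(F)
  v <- (colSums(F^2) - n * m^2) / (n - 1)
  t <- ifelse(v > 1e-300, m / sqrt(v / n), NA_real_)
  new("TMap", t = matrix(t, nV, nT), df = as.integer(n - 1),
      tail = "positive")
}

#' Form spatiotemporal clusters from a t-map
#'
#' The cluster-forming threshold \code{cftP} (a point-wise one-tailed p)
#' is converted to the Student-t quantile at the map's df; supra-threshold
#' (vertex, time) points are grouped into connected components, where two
#' points are connected if they share a mesh edge at the same sample or
#' the same vertex at adjacent samples. Each cluster's mass is its summed
#' t. NA t-values are treated as sub-threshold.
#'
#' @param tmap a \code{\linkS4class{TMap}}.
#' @param mesh the \code{\linkS4class{CorticalMesh}} supplying contiguity.
#' @param cftP cluster-forming threshold in (0, 0.5); default 0.01.
#' @return list of clusters, each \code{list(members, mass)} with
#'   \code{members} a 2-column (vertex, timeIdx) matrix; ordered by
#'   decreasing mass. Empty list when nothing is supra-threshold.
#' @export
formClusters <- function(tmap, mesh, cftP = 0.01) {
  stopifnot(is(tmap, "TMap"), is(mesh, "CorticalMesh"))
  if (cftP <= 0 || cftP >= 0.5) stop("cftP must lie in (0, 0.5)")
  thr <- qt(1 - cftP, df = tmap@df)
  nb <- meshNeighborList(mesh)
  lab <- cluster_label_cpp(tmap@t, thr, nb)
  masses <- lab$masses
  if (!length(masses)) return(list())
  out <- lapply(seq_along(masses), function(k) {
    w <- which(lab$labels == k, arr.ind = TRUE)
    colnames(w) <- c("vertex", "timeIdx")
    list(members = w, mass = masses[k])
  })
  out[order(masses, decreasing = TRUE)]
}

#' Cluster-level inference by sign-flip permutation
#'
#' Under the null that the model fit is zero, each subject's whole fit map
#' is multiplied by an independent random sign (whole-map flips preserve
#' the spatial covariance under H0); the group t-map and clusters are
#' recomputed, and the maximum cluster mass (0 when none) enters the null
#' distribution. Each observed cluster's corrected p is the add-one
#' estimator \eqn{(1 + \#\{null \ge mass\}) / (1 + nPerm)}, so p is never
#' exactly 0 and the observed labeling is not otherwise added to the null.
#'
#' @param maps a \code{\linkS4class{SearchlightMap}}.
#' @param mesh the \code{\linkS4class{CorticalMesh}}.
#' @param cftP cluster-forming threshold (point-wise one-tailed p).
#' @param nPerm number of permutations (1000 for reporting; at least 100
#'   recommended, smaller allowed for smoke tests).
#' @param seed RNG seed; identical seed gives an identical null.
#' @return a \code{\linkS4class{ClusterResult}}
#' @export
signFlipPermutation <- function(maps, mesh, cftP = 0.01, nPerm = 1000,
                                seed = 1) {
  stopifnot(is(maps, "SearchlightMap"), is(mesh, "CorticalMesh"))
  n <- dim(maps@fits)[1]
  if (n < 5)
    warning(sprintf("only %d subjects: the sign-flip null has at most 2^%d support",
                    n, n))
  tm <- groupTMap(maps)
  obs <- formClusters(tm, mesh, cftP)
  thr <- qt(1 - cftP, df = tm@df)
  nV <- dim(maps@fits)[2]
  nT <- dim(maps@fits)[3]
  F <- matrix(maps@fits, nrow = n)
  nb <- meshNeighborList(mesh)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * nPerm, replace = TRUE), n, nPerm)
  null <- perm_max_mass_cpp(F, signs, nV, nT, thr, nb)
  clusters <- lapply(obs, function(cl) {
    cl$p <- (1 + sum(null >= cl$mass)) / (1 + nPerm)
    cl
  })
  new("ClusterResult", clusters = clusters, cftP = cftP, tThreshold = thr,
      nPerm = as.integer(nPerm), nullMaxMasses = as.numeric(null),
      seed = as.integer(seed), df = tm@df, timeMs = maps@timeMs)
}

#' Tabulate clusters with significance tiers
#'
#' @param result a \code{\linkS4class{ClusterResult}}.
#' @param alpha corrected significance level (default 0.05).
#' @param marginal upper bound of the "marginally significant" tier
#'   (default 0.06): clusters with \eqn{alpha < p \le marginal}.
#' @return data frame with one row per cluster: onset/offset in ms,
#'   vertex extent, point count, mass, p and tier
#'   (\code{significant} / \code{marginal} / \code{ns})
#' @export
reportClusters <- function(result, alpha = 0.05, marginal = 0.06) {
  stopifnot(is(result, "ClusterResult"))
  if (!length(result@clusters))
    return(data.frame(cluster = integer(), onset_ms = numeric(),
                      offset_ms = numeric(), n_vertices = integer(),
                      n_points = integer(), mass = numeric(), p = numeric(),
                      tier = character()))
  rows <- lapply(seq_along(result@clusters), function(i) {
    cl <- result@clusters[[i]]
    ts <- result@timeMs[cl$members[, "timeIdx"]]
    tier <- if (cl$p <= alpha) "significant"
            else if (cl$p <= marginal) "marginal" else "ns"
    data.frame(cluster = i, onset_ms = min(ts), offset_ms = max(ts),
               n_vertices = length(unique(cl$members[, "vertex"])),
               n_points = nrow(cl$members), mass = cl$mass, p = cl$p,
               tier = tier)
  })
  do.call(rbind, rows)
}
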