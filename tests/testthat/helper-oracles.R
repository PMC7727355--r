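## Independent reference implementations and small fixture builders shared
## across test files. These deliberately use a different code path from the
## package (base lm/rank, plain BFS) so agreement is meaningful.

rand_simplex <- function(n) {
  x <- rgamma(n, 1)
  x / sum(x)
}

## RDM from an explicit dissimilarity matrix
rdm_from_matrix <- function(d, kind = "model",
                            labels = paste0("t", seq_len(nrow(d)))) {
  new("RDM", labels = labels, d = d, kind = kind)
}

## random symmetric zero-diagonal RDM over n labels
rand_rdm <- function(n, kind = "model") {
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- runif(n * (n - 1) / 2)
  rdm_from_matrix(d + t(d), kind)
}

## brute-force partial Spearman: rank, residualize with lm, Pearson
oracle_partial_spearman <- function(data, model, covariates = list()) {
  tri <- function(x) x@d[lower.tri(x@d)]
  dv <- rank(tri(data))
  mv <- rank(tri(model))
  if (!length(covariates)) return(cor(dv, mv))
  X <- sapply(covariates, function(cv) rank(tri(cv)))
  rd <- residuals(lm(dv ~ X))
  rm_ <- residuals(lm(mv ~ X))
  cor(rd, rm_)
}

## brute-force connected components of a supra-threshold (vertex, time)
## map: plain queue BFS over mesh edges at equal samples and equal
## vertices at adjacent samples
oracle_clusters <- function(tmat, thr, edges) {
  V <- nrow(tmat); Tn <- ncol(tmat)
  supra <- !is.na(tmat) & tmat >= thr
  adj <- vector("list", V)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  seen <- matrix(FALSE, V, Tn)
  out <- list()
  for (t in seq_len(Tn)) for (v in seq_len(V)) {
    if (!supra[v, t] || seen[v, t]) next
    queue <- list(c(v, t))
    seen[v, t] <- TRUE
    members <- NULL
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, p)
      for (w in adj[[p[1]]])
        if (supra[w, p[2]] && !seen[w, p[2]]) {
          seen[w, p[2]] <- TRUE; queue <- c(queue, list(c(w, p[2])))
        }
      for (dt in c(-1, 1)) {
        tt <- p[2] + dt
        if (tt >= 1 && tt <= Tn && supra[p[1], tt] && !seen[p[1], tt]) {
          seen[p[1], tt] <- TRUE; queue <- c(queue, list(c(p[1], tt)))
        }
      }
    }
    out[[length(out) + 1]] <-
      list(members = members, mass = sum(tmat[members]))
  }
  out
}

## canonical representation of a cluster set for comparison
cluster_signature <- function(cl) {
  sig <- lapply(cl, function(x) {
    m <- x$members[order(x$members[, 1], x$members[, 2]), , drop = FALSE]
    paste(paste(m[, 1], m[, 2], sep = ","), collapse = ";")
  })
  masses <- vapply(cl, `[[`, numeric(1), "mass")
  o <- order(unlist(sig))
  list(members = unlist(sig)[o], masses = round(masses[o], 8))
}

## label-permutation-invariant purity of a hard topic assignment
topic_purity <- function(assigned, truth) {
  tab <- table(assigned, truth)
  sum(apply(tab, 1, max)) / length(truth)
}

dice_points <- function(a, b) {
  key <- function(m) paste(m[, 1], m[, 2])
  2 * length(intersect(key(a), key(b))) / (nrow(a) + nrow(b))
}

## small line mesh: vertices on a line 5 mm apart, chain edges
line_mesh <- function(n, spacing = 5) {
  coords <- cbind(seq_len(n) * spacing, 0, 0)
  edges <- if (n > 1) cbind(seq_len(n - 1), seq_len(n - 1) + 1)
           else matrix(integer(), 0, 2)
  corticalMesh(coords, edges)
}

## SourceEpochs around an explicit trials x vertices x time array
epochs_from_array <- function(X, subject = "sub01",
                              epochName = "verb_onset",
                              timeMs = seq(0, 600, length.out = dim(X)[3])) {
  new("SourceEpochs", subjectId = subject, data = X, timeMs = timeMs,
      epochName = epochName,
      trialIds = sprintf("s%04d", seq_len(dim(X)[1])))
}
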