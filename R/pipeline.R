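## End-to-end orchestration: the model-by-epoch analysis schedule,
## input validation, and the run driver.

.SCHEDULE <- list(
  SNP_to_verbs   = c("SN_onset", "verb_onset"),
  SNP_to_CNs     = c("SN_onset", "verb_onset"),
  SNPverb_to_CNs = c("verb_onset", "CN_onset"),
  mismatch_CN    = c("CN_onset"))

#' The default model-by-epoch analysis plan
#'
#' The three entropy models are tested in the epochs where their
#' constraint is hypothesized to be active — the SNP-based models in the
#' subject-noun and verb epochs, the SNP + verb model in the verb and
#' complement-noun epochs — and the mismatch model only in the
#' complement-noun epoch (it needs the heard complement noun). The default
#' plan expands to the 6 entropy model-epoch runs plus the one mismatch
#' run.
#'
#' @param cftP cluster-forming threshold (point-wise one-tailed p).
#' @param nPerm sign-flip permutations per run.
#' @param seed base RNG seed (each run derives its own from it).
#' @param alpha,marginal significance tiers for reporting.
#' @return data frame plan with one row per (model, epoch) run plus the
#'   stats configuration as attributes
#' @export
analysisPlan <- function(cftP = 0.01, nPerm = 1000, seed = 7,
                         alpha = 0.05, marginal = 0.06) {
  rows <- do.call(rbind, lapply(names(.SCHEDULE), function(m) {
    data.frame(model_name = m,
               metric_kind = if (m == "mismatch_CN") "mismatch" else "entropy",
               epoch_name = .SCHEDULE[[m]], stringsAsFactors = FALSE)
  }))
  structure(rows, cftP = cftP, nPerm = nPerm, seed = seed,
            alpha = alpha, marginal = marginal)
}

#' Validate an analysis plan against the model-by-epoch schedule
#'
#' @param plan a plan data frame (see \code{\link{analysisPlan}}).
#' @return the plan, invisibly; errors on any pair outside the schedule
#' @export
validateAnalysisPlan <- function(plan) {
  for (i in seq_len(nrow(plan))) {
    m <- plan$model_name[i]
    e <- plan$epoch_name[i]
    if (is.null(.SCHEDULE[[m]]))
      stop(sprintf("unknown model '%s' in the analysis plan", m))
    if (!e %in% .SCHEDULE[[m]])
      stop(sprintf(
        "model '%s' is not scheduled in epoch '%s' (allowed: %s)",
        m, e, paste(.SCHEDULE[[m]], collapse = ", ")))
  }
  invisible(plan)
}

#' Validate a synthetic (or assembled) input bundle
#'
#' Fail-fast checks before a run: blend simplex sums, trial-id alignment
#' between the stimulus table and every subject's epochs, epoch windows
#' inside 0-600 ms, mesh integrity, and non-negative completion counts.
#'
#' @param bundle a dataset bundle as produced by
#'   \code{\link{simulateDataset}}.
#' @param stopOnError error (with all violations listed) instead of
#'   returning them.
#' @return data frame of violations (zero rows when clean)
#' @export
validateInputs <- function(bundle, stopOnError = FALSE) {
  bad <- list()
  note <- function(check, detail)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail,
                                           stringsAsFactors = FALSE)
  for (bn in names(bundle$blends))
    for (b in bundle$blends[[bn]]) {
      s <- sum(b@probs)
      if (abs(s - 1) > 1e-9 || any(b@probs < 0))
        note("blend_simplex", sprintf("%s/%s sums to %.12f", bn, b@stimulusId, s))
    }
  ids <- bundle$stimuli$stimulus_id
  for (en in names(bundle$epochs))
    for (ep in bundle$epochs[[en]]) {
      if (!all(ep@trialIds %in% ids))
        note("trial_ids", sprintf("%s/%s has trial ids not in the stimulus table",
                                  en, ep@subjectId))
      if (min(ep@timeMs) < 0 || max(ep@timeMs) > 600)
        note("epoch_window", sprintf("%s/%s outside 0-600 ms", en, ep@subjectId))
    }
  if (!is.null(bundle$mesh)) {
    msg <- validObject(bundle$mesh, test = TRUE)
    if (!isTRUE(msg)) note("mesh", paste(msg, collapse = "; "))
  }
  if (!is.null(bundle$completions)) {
    for (st in c("stage1", "stage2"))
      for (cs in bundle$completions[[st]])
        if (length(cs@responses) && any(cs@responses < 1))
          note("completion_counts", sprintf("%s: count below 1", cs@stimulusId))
  }
  out <- if (length(bad)) do.call(rbind, bad)
         else data.frame(check = character(), detail = character())
  if (stopOnError && nrow(out))
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", out$check, out$detail), collapse = "\n"))
  out
}

#' Run a model-by-epoch analysis plan end to end
#'
#' For each (model, epoch) run: build the model RDM from the bundle's
#' metric table, the epoch's covariate RDMs (alignment-word log frequency
#' and SNP + verb repetition), per-subject searchlight fit maps, the group
#' t-map, sign-flip cluster permutation, and the cluster report. Each run
#' derives its permutation seed deterministically from the plan seed, so
#' re-running a plan reproduces every output.
#'
#' @param plan plan data frame from \code{\link{analysisPlan}}.
#' @param bundle dataset bundle (see \code{\link{simulateDataset}}).
#' @param outDir optional directory; when given, per-run cluster reports
#'   (TSV) and a JSON manifest are written into it.
#' @param rMm,rMs searchlight radii (mm / ms).
#' @return list with per-run results (\code{maps}, \code{tmap},
#'   \code{result}, \code{report}) keyed by "model@epoch", and the
#'   manifest
#' @export
runPlan <- function(plan, bundle, outDir = NULL, rMm = 10, rMs = 30) {
  validateAnalysisPlan(plan)
  validateInputs(bundle, stopOnError = TRUE)
  cftP <- attr(plan, "cftP") %||% 0.01
  nPerm <- attr(plan, "nPerm") %||% 1000
  seed <- attr(plan, "seed") %||% 7
  alpha <- attr(plan, "alpha") %||% 0.05
  marginal <- attr(plan, "marginal") %||% 0.06
  mesh <- bundle$mesh
  runs <- list()
  excl <- list()
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  for (i in seq_len(nrow(plan))) {
    m <- plan$model_name[i]
    e <- plan$epoch_name[i]
    mt <- bundle$metricTables[[m]]
    if (is.null(mt)) stop(sprintf("no metric table for model '%s'", m))
    mrdm <- modelRDM(mt)
    cov <- covariateRDMs(bundle$stimuli, e, labels = mrdm@labels)
    eps <- bundle$epochs[[e]]
    if (is.null(eps)) stop(sprintf("no epochs for alignment point '%s'", e))
    index <- buildSearchlightIndex(mesh, eps[[1]]@timeMs, rMm, rMs)
    maps <- subjectFitMaps(eps, index, mrdm, cov)
    maps@modelName <- m
    res <- signFlipPermutation(maps, mesh, cftP = cftP, nPerm = nPerm,
                               seed = seed + 101 * i)
    rep_ <- reportClusters(res, alpha = alpha, marginal = marginal)
    key <- paste0(m, "@", e)
    runs[[key]] <- list(model = m, epoch = e, maps = maps,
                        tmap = groupTMap(maps), result = res, report = rep_)
    excl[[key]] <- list(
      n_stimuli_in_model = length(mrdm@labels),
      n_subjects_used = length(maps@subjectIds))
    if (!is.null(outDir))
      write.table(rep_, file.path(outDir, paste0(key, "_clusters.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("blendRSA")),
    plan = plan[, c("model_name", "metric_kind", "epoch_name")],
    stats = list(cftP = cftP, nPerm = nPerm, seed = seed, alpha = alpha,
                 marginal = marginal, rMm = rMm, rMs = rMs),
    generator = bundle$config[setdiff(names(bundle$config),
                                      c("complementProbs"))],
    inputs = list(
      n_stimuli = nrow(bundle$stimuli),
      n_vertices = nrow(mesh@coords),
      epochs = names(bundle$epochs),
      checksum_stimuli = .checksum(bundle$stimuli$sn_logfreq),
      checksum_mesh = .checksum(bundle$mesh@coords)),
    runs = excl)
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(runs = runs, manifest = manifest)
}

## order-sensitive plain checksum for the manifest; not cryptographic
.checksum <- function(x) {
  v <- as.numeric(x)
  sprintf("%.0f", sum(v * seq_along(v)) * 1e6 %% 2^31)
}
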