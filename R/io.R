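## Plain-text persistence. Matrices are written as TSV with 17 significant
## digits (lossless for doubles), metadata as JSON sidecars, so every
## artifact is diffable and round-trips bit-exactly.

.writeMatrixTSV <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(colnames(m)))
    writeLines(paste(colnames(m), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = "\t"), con)
  invisible(path)
}

.readMatrixTSV <- function(path, header = FALSE) {
  lines <- readLines(path)
  start <- if (header) 2L else 1L
  cn <- if (header) strsplit(lines[1], "\t", fixed = TRUE)[[1]] else NULL
  rows <- lapply(lines[seq(start, length(lines))],
                 function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  m <- do.call(rbind, rows)
  colnames(m) <- cn
  m
}

#' Persist / load a topic model
#'
#' Writes the three probability tables as TSV and the vocabularies plus
#' training configuration as a JSON sidecar under \code{dir}.
#'
#' @param model a \code{\linkS4class{TopicModel}}.
#' @param dir directory (created if missing).
#' @return the directory (write) or the reconstructed model (read)
#' @export
writeTopicModel <- function(model, dir) {
  stopifnot(is(model, "TopicModel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeMatrixTSV(unname(model@contextTopic),
                  file.path(dir, "context_topic.tsv"))
  .writeMatrixTSV(unname(model@topicTarget),
                  file.path(dir, "topic_target.tsv"))
  .writeMatrixTSV(matrix(model@topicPrior, 1), file.path(dir, "topic_prior.tsv"))
  jsonlite::write_json(
    list(sliceName = model@sliceName, nTopics = model@nTopics,
         contexts = rownames(model@contextTopic),
         targets = colnames(model@topicTarget),
         trainingConfig = model@trainingConfig),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeTopicModel
#' @export
readTopicModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  ct <- .readMatrixTSV(file.path(dir, "context_topic.tsv"))
  tt <- .readMatrixTSV(file.path(dir, "topic_target.tsv"))
  prior <- as.numeric(.readMatrixTSV(file.path(dir, "topic_prior.tsv")))
  rownames(ct) <- meta$contexts
  colnames(tt) <- meta$targets
  new("TopicModel", sliceName = meta$sliceName,
      nTopics = as.integer(meta$nTopics), contextTopic = ct,
      topicTarget = tt, topicPrior = prior,
      trainingConfig = as.list(meta$trainingConfig))
}

#' Persist / load one subject's source epochs together with the mesh
#'
#' One directory holds `mesh_coords.tsv`, `mesh_edges.tsv`, `time_ms.tsv`
#' and, per subject, `epochs_<subject>.tsv` (one row per trial, member
#' amplitudes flattened vertex-major) plus a JSON sidecar with ids and
#' dimensions.
#'
#' @param epochsList list of \code{\linkS4class{SourceEpochs}}.
#' @param mesh the shared \code{\linkS4class{CorticalMesh}}.
#' @param dir directory (created if missing).
#' @return the directory (write) or a list \code{(epochs, mesh)} (read)
#' @export
writeEpochsBundle <- function(epochsList, mesh, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeMatrixTSV(mesh@coords, file.path(dir, "mesh_coords.tsv"))
  .writeMatrixTSV(mesh@edges * 1.0, file.path(dir, "mesh_edges.tsv"))
  .writeMatrixTSV(matrix(epochsList[[1]]@timeMs, 1),
                  file.path(dir, "time_ms.tsv"))
  meta <- list()
  for (ep in epochsList) {
    d <- dim(ep@data)
    flat <- matrix(ep@data, d[1], d[2] * d[3])
    .writeMatrixTSV(flat, file.path(dir, sprintf("epochs_%s.tsv", ep@subjectId)))
    meta[[ep@subjectId]] <- list(subjectId = ep@subjectId,
                                 epochName = ep@epochName,
                                 trialIds = ep@trialIds,
                                 dim = d)
  }
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeEpochsBundle
#' @export
readEpochsBundle <- function(dir) {
  coords <- .readMatrixTSV(file.path(dir, "mesh_coords.tsv"))
  edges <- .readMatrixTSV(file.path(dir, "mesh_edges.tsv"))
  tm <- as.numeric(.readMatrixTSV(file.path(dir, "time_ms.tsv")))
  mesh <- corticalMesh(coords, edges)
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  epochs <- lapply(meta, function(mi) {
    flat <- .readMatrixTSV(file.path(dir, sprintf("epochs_%s.tsv", mi$subjectId)))
    new("SourceEpochs", subjectId = mi$subjectId,
        data = array(flat, mi$dim), timeMs = tm, epochName = mi$epochName,
        trialIds = as.character(mi$trialIds))
  })
  list(epochs = unname(epochs), mesh = mesh)
}

#' Persist / load an RDM
#'
#' @param x an \code{\linkS4class{RDM}}.
#' @param path TSV path; labels and kind go into a leading comment-free
#'   header block handled by the reader.
#' @return the path (write) or the \code{RDM} (read)
#' @export
writeRDM <- function(x, path) {
  stopifnot(is(x, "RDM"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(x@kind, paste(x@labels, collapse = "\t")), con)
  for (i in seq_len(nrow(x@d)))
    writeLines(paste(sprintf("%.17g", x@d[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeRDM
#' @export
readRDM <- function(path) {
  lines <- readLines(path)
  kind <- lines[1]
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  d <- do.call(rbind, lapply(lines[-(1:2)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  new("RDM", labels = labels, d = d, kind = kind)
}
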