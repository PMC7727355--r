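#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults matching the study
#' design the package models: 200 sentences in repetition groups of 4
#' (each subject-noun-phrase + verb combination occurs four times), two
#' completion studies with 24 and 31 respondents, 100 topics, 0-600 ms
#' epochs, and desk-scale source-space dimensions (300 vertices, 100 Hz
#' sampling, 12 subjects).
#'
#' @param seed master RNG seed; every generator operation derives its own
#'   stream from it and is fully deterministic.
#' @param nStimuli number of sentences (divisible by \code{repGroupSize}).
#' @param nSubjects number of simulated EMEG subjects.
#' @param nVertices mesh size (random points in a 100 mm box).
#' @param samplingRate source sampling rate in Hz (100 Hz gives 61 samples
#'   over the 0-600 ms epoch).
#' @param nTopics latent topics in the synthetic corpus and topic models.
#' @param repGroupSize size of each SNP + verb repetition group.
#' @param stage1N,stage2N responses per stimulus in the two completion
#'   studies.
#' @param stage2Sharpening concentration multiplier applied to each
#'   stimulus's latent constraint before drawing second-stage responses;
#'   values > 1 lower the expected entropy of the SNP + verb constraint
#'   relative to the SNP constraint (1 = null control).
#' @param injection list: \code{regionRadiusMm} (ball radius defining the
#'   injected vertex set), \code{windowMs} (injection time window),
#'   \code{effectSize} (signal-to-noise ratio; 0 = pure noise),
#'   \code{targetModelName} (which metric drives the injected geometry),
#'   \code{epochName} (which epoch carries the injection).
#' @param noiseSd iid Gaussian noise SD of the source amplitudes.
#' @param backgroundSd SD of the smooth background shared by all trials.
#' @param meshKnn neighbors per vertex for the mesh adjacency.
#' @param corpus list: \code{contextsPerTopic}, \code{targetsPerTopic},
#'   \code{withinRate} (Poisson rate inside a topic block),
#'   \code{noiseRate} (Poisson rate across blocks; 0 = separable).
#' @param completionConc Dirichlet concentration of the per-stimulus
#'   latent constraint over topics (smaller = sharper constraints).
#' @param pObject probability that a second-stage response is flagged as
#'   an object noun (non-object responses are filtered downstream).
#' @param complementProbs sentence complement-type mixture; DO and PP
#'   sentences have an identifiable complement noun (about 64% under the
#'   default, matching the roughly two-thirds CN-bearing share of the
#'   modeled stimulus set).
#' @param lda list of topic-model training settings
#'   (\code{nIter}, \code{weightScale}) used by
#'   \code{\link{simulateDataset}}.
#' @return a validated list of class \code{"generatorConfig"}
#' @export
generatorConfig <- function(seed = 1, nStimuli = 200, nSubjects = 12,
                            nVertices = 300, samplingRate = 100,
                            nTopics = 100, repGroupSize = 4,
                            stage1N = 24, stage2N = 31,
                            stage2Sharpening = 2,
                            injection = list(),
                            noiseSd = 1, backgroundSd = 0.5, meshKnn = 5,
                            corpus = list(),
                            completionConc = 0.5, pObject = 0.9,
                            complementProbs = c(DO = 0.50, PP = 0.14,
                                                SC = 0.18, INF = 0.18),
                            lda = list()) {
  inj <- modifyList(list(regionRadiusMm = 20, windowMs = c(150, 450),
                         effectSize = 0.8, targetModelName = "SNPverb_to_CNs",
                         epochName = "verb_onset"), injection)
  corp <- modifyList(list(contextsPerTopic = 4, targetsPerTopic = 6,
                          withinRate = 20, noiseRate = 0.1), corpus)
  ldac <- modifyList(list(nIter = 300, weightScale = 10), lda)
  cfg <- list(seed = as.integer(seed), nStimuli = as.integer(nStimuli),
              nSubjects = as.integer(nSubjects),
              nVertices = as.integer(nVertices),
              samplingRate = samplingRate, nTopics = as.integer(nTopics),
              repGroupSize = as.integer(repGroupSize),
              stage1N = as.integer(stage1N), stage2N = as.integer(stage2N),
              stage2Sharpening = stage2Sharpening, injection = inj,
              noiseSd = noiseSd, backgroundSd = backgroundSd,
              meshKnn = as.integer(meshKnn), corpus = corp,
              completionConc = completionConc, pObject = pObject,
              complementProbs = complementProbs, lda = ldac)
  with(cfg, {
    stopifnot(nStimuli > 0, nSubjects > 0, nVertices > 0, nTopics > 0,
              samplingRate > 0, repGroupSize > 0,
              stage1N > 0, stage2N > 0, stage2Sharpening > 0,
              injection$effectSize >= 0, noiseSd > 0)
    if (nStimuli %% repGroupSize != 0)
      stop("nStimuli must be divisible by repGroupSize")
    if (injection$windowMs[1] < 0 || injection$windowMs[2] > 600)
      stop("injection window must lie within the 0-600 ms epoch")
  })
  structure(cfg, class = c("generatorConfig", "list"))
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

#' Synthetic stimulus metadata
#'
#' Emulates the sentence-set design: \code{nStimuli} sentences in
#' repetition groups sharing the SNP + verb combination, word durations
#' drawn from Gaussians matching the modeled set (subject noun
#' 432 +/- 142 ms, verb 422 +/- 111 ms, complement word 401 +/- 115 ms,
#' truncated at 100 ms), uniqueness points at 80% of each word's duration,
#' standard-normal log lexical frequencies, and a complement-type mixture
#' in which DO/PP sentences (about 64%) carry an identifiable complement
#' noun.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @return data frame with one row per stimulus: word identifiers, onsets,
#'   uniqueness points, log frequencies, repetition group, complement type
#'   and \code{has_cn}
#' @export
makeStimuli <- function(cfg) {
  .withSeed(cfg$seed * 17 + 1, {
    n <- cfg$nStimuli
    gsz <- cfg$repGroupSize
    nG <- n %/% gsz
    grp <- rep(seq_len(nG), each = gsz)
    snDur <- pmax(100, rnorm(nG, 432, 142))[grp]
    vbDur <- pmax(100, rnorm(nG, 422, 111))[grp]
    cnDur <- pmax(100, rnorm(n, 401, 115))
    snOn <- rep(0, n)
    vbOn <- snOn + snDur
    cnOn <- vbOn + vbDur + 120        # complement function word gap
    ## complement types are a design property: allocate fixed counts by
    ## largest remainder, then shuffle across stimuli
    quota <- cfg$complementProbs / sum(cfg$complementProbs) * n
    cnts <- floor(quota)
    rem <- n - sum(cnts)
    if (rem > 0) {
      extra <- order(quota - cnts, decreasing = TRUE)[seq_len(rem)]
      cnts[extra] <- cnts[extra] + 1
    }
    ctype <- sample(rep(names(cfg$complementProbs), cnts))
    data.frame(
      stimulus_id = sprintf("s%04d", seq_len(n)),
      sn_word = sprintf("sn_g%03d", grp),
      verb_word = sprintf("verb_g%03d", grp),
      cn_word = sprintf("cn_s%04d", seq_len(n)),
      rep_group = sprintf("g%03d", grp),
      complement_type = ctype,
      has_cn = ctype %in% c("DO", "PP"),
      sn_onset_ms = snOn, verb_onset_ms = vbOn, cn_onset_ms = cnOn,
      sn_up_ms = snOn + 0.8 * snDur, verb_up_ms = vbOn + 0.8 * vbDur,
      cn_up_ms = cnOn + 0.8 * cnDur,
      sn_logfreq = rnorm(nG)[grp], verb_logfreq = rnorm(nG)[grp],
      cn_logfreq = rnorm(n),
      stringsAsFactors = FALSE)
  })
}

#' Synthetic block-structured co-occurrence corpus
#'
#' Builds both tensor slices with an identifiable latent topic structure:
#' topic k owns disjoint subject-noun, verb and complement-noun word sets;
#' within-block counts are Poisson(\code{withinRate}) and cross-block
#' counts Poisson(\code{noiseRate}). The first slice (SN_V) pairs subject
#' nouns with verbs; the second (SNV_CN) pairs subject nouns and verbs
#' with complement nouns. The latent word-to-topic assignment is returned
#' so topic recovery can be scored.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @return list with \code{sn_v} and \code{snv_cn}
#'   \code{\linkS4class{CooccurrenceTable}}s and a \code{latent} list
#'   (word sets and topic assignments per vocabulary)
#' @export
makeCorpus <- function(cfg) {
  .withSeed(cfg$seed * 17 + 2, {
    K <- cfg$nTopics
    if (K < 2) stop("block corpus needs at least 2 topics")
    nc <- cfg$corpus$contextsPerTopic
    nt <- cfg$corpus$targetsPerTopic
    sns <- sprintf("sn_k%02d_%02d", rep(seq_len(K), each = nc),
                   rep(seq_len(nc), K))
    verbs <- sprintf("verb_k%02d_%02d", rep(seq_len(K), each = nt),
                     rep(seq_len(nt), K))
    cns <- sprintf("cn_k%02d_%02d", rep(seq_len(K), each = nt),
                   rep(seq_len(nt), K))
    topicOf <- function(words) as.integer(sub("^.*_k(\\d+)_.*$", "\\1", words))
    blockCounts <- function(ctx, tgt) {
      tc <- topicOf(ctx); tt <- topicOf(tgt)
      same <- outer(tc, tt, "==")
      m <- matrix(rpois(length(ctx) * length(tgt),
                        ifelse(same, cfg$corpus$withinRate,
                               cfg$corpus$noiseRate)),
                  length(ctx), length(tgt), dimnames = list(ctx, tgt))
      m
    }
    list(sn_v = cooccurrenceTable(blockCounts(sns, verbs), "SN_V"),
         snv_cn = cooccurrenceTable(blockCounts(c(sns, verbs), cns), "SNV_CN"),
         latent = list(sns = sns, verbs = verbs, cns = cns,
                       topicOfSN = topicOf(sns), topicOfVerb = topicOf(verbs),
                       topicOfCN = topicOf(cns)))
  })
}

#' Synthetic sentence-completion responses for both stages
#'
#' Per stimulus, a latent constraint distribution over topics is drawn
#' (Dirichlet with concentration \code{completionConc}); first-stage verb
#' responses are multinomial draws from the induced word distribution, and
#' second-stage complement-noun responses are drawn from the same latent
#' distribution sharpened by \code{stage2Sharpening} (probabilities raised
#' to that power and renormalized), so an expected entropy reduction from
#' the SNP constraint to the SNP + verb constraint holds by construction
#' when sharpening > 1 and is absent at 1. Second-stage responses are
#' flagged as object nouns with probability \code{pObject}.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @param stimuli stimulus table from \code{\link{makeStimuli}}
#' @param corpus corpus list from \code{\link{makeCorpus}}
#' @return list: \code{responses} (long data frame
#'   `stimulus_id stage response_word count is_object`) and \code{truth}
#'   (latent topic distributions \code{q1}, \code{q2} per stimulus and
#'   their Shannon entropies)
#' @export
simulateCompletions <- function(cfg, stimuli, corpus) {
  .withSeed(cfg$seed * 17 + 3, {
    K <- cfg$nTopics
    n <- nrow(stimuli)
    q1 <- matrix(rgamma(n * K, shape = cfg$completionConc), n, K)
    q1 <- q1 / rowSums(q1)
    q2 <- q1^cfg$stage2Sharpening
    q2 <- q2 / rowSums(q2)
    wordDist <- function(q, words, topicOf) {
      p <- q[topicOf] / tabulate(topicOf, K)[topicOf]
      p / sum(p)
    }
    rows <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      id <- stimuli$stimulus_id[i]
      p1 <- wordDist(q1[i, ], corpus$latent$verbs, corpus$latent$topicOfVerb)
      c1 <- as.integer(rmultinom(1, cfg$stage1N, p1))
      nz <- which(c1 > 0)
      rows[[2 * i - 1]] <- data.frame(
        stimulus_id = id, stage = "SNP",
        response_word = corpus$latent$verbs[nz], count = c1[nz],
        is_object = NA, stringsAsFactors = FALSE)
      p2 <- wordDist(q2[i, ], corpus$latent$cns, corpus$latent$topicOfCN)
      c2 <- as.integer(rmultinom(1, cfg$stage2N, p2))
      nz <- which(c2 > 0)
      nObj <- rbinom(length(nz), c2[nz], cfg$pObject)
      sub <- data.frame(stimulus_id = id, stage = "SNP_VERB",
                        response_word = corpus$latent$cns[nz],
                        count = nObj, is_object = TRUE,
                        stringsAsFactors = FALSE)
      nonObj <- c2[nz] - nObj
      if (any(nonObj > 0))
        sub <- rbind(sub, data.frame(stimulus_id = id, stage = "SNP_VERB",
                                     response_word = corpus$latent$cns[nz[nonObj > 0]],
                                     count = nonObj[nonObj > 0],
                                     is_object = FALSE,
                                     stringsAsFactors = FALSE))
      rows[[2 * i]] <- sub[sub$count > 0, , drop = FALSE]
    }
    ent <- function(m) apply(m, 1, function(p) {
      p <- p[p > 0]; -sum(p * log(p))
    })
    list(responses = do.call(rbind, rows),
         truth = list(q1 = q1, q2 = q2,
                      entropy1 = setNames(ent(q1), stimuli$stimulus_id),
                      entropy2 = setNames(ent(q2), stimuli$stimulus_id)))
  })
}

#' Synthetic cortical mesh
#'
#' Random vertex coordinates in a 100 mm box with symmetric
#' k-nearest-neighbor adjacency: a random geometric graph sufficient for
#' every geometry-dependent step (searchlight radii, cluster contiguity),
#' standing in for a real cortical surface, which it does not attempt to
#' model.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @return a \code{\linkS4class{CorticalMesh}}
#' @export
simulateMesh <- function(cfg) {
  .withSeed(cfg$seed * 17 + 4, {
    n <- cfg$nVertices
    coords <- matrix(runif(n * 3, 0, 100), n, 3)
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    k <- min(cfg$meshKnn, n - 1)
    edges <- do.call(rbind, lapply(seq_len(n), function(v) {
      cbind(v, order(d[v, ])[seq_len(k)])
    }))
    corticalMesh(coords, edges)
  })
}

#' Synthetic source-space epochs with an injected representational effect
#'
#' Outside the injection, the data are iid Gaussian noise plus a smooth
#' background shared by all trials. Inside the injected vertex set and
#' time window, trial t receives the unit-magnitude pattern
#' \eqn{effectSize [\cos\theta_t u_1 + \sin\theta_t u_2]} with fixed
#' orthonormal patterns \eqn{u_1, u_2} and \eqn{\theta_t} an affine map of
#' the trial's true metric value into [0, pi/2]. Because
#' \eqn{1 - \cos(\Delta\theta)} is monotone on that range, the Pearson
#' distance between trials increases monotonically with the absolute
#' metric difference, making the absolute-difference model RDM
#' recoverable; an amplitude-coded injection would be invisible to a
#' correlation-distance data RDM. The injected signal is shared across
#' subjects; noise is drawn independently per subject.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @param stimuli stimulus table (its ids become trial ids).
#' @param trueMetric named numeric vector of per-stimulus metric values
#'   driving the injection geometry (ignored when
#'   \code{injection$effectSize} is 0).
#' @param mesh optional \code{\linkS4class{CorticalMesh}} (defaults to
#'   \code{\link{simulateMesh}}).
#' @param epochName alignment point stored on the epochs (defaults to the
#'   configured injection epoch).
#' @param inject whether to add the injected signal (FALSE for the other
#'   epochs of a full dataset).
#' @return list: \code{epochs} (list of \code{\linkS4class{SourceEpochs}},
#'   one per subject), \code{mesh}, and \code{truth} (injected vertex set,
#'   window samples and ms, theta per trial, the metric used)
#' @export
simulateSourceEpochs <- function(cfg, stimuli, trueMetric = NULL,
                                 mesh = NULL, epochName = NULL,
                                 inject = TRUE) {
  if (is.null(mesh)) mesh <- simulateMesh(cfg)
  if (is.null(epochName)) epochName <- cfg$injection$epochName
  .withSeed(cfg$seed * 17 + 5 + match(epochName, c("SN_onset", "verb_onset",
                                                   "CN_onset")), {
    n <- nrow(stimuli)
    ids <- stimuli$stimulus_id
    tm <- seq(0, 600, by = 1000 / cfg$samplingRate)
    nV <- nrow(mesh@coords)
    nT <- length(tm)
    center <- sample(nV, 1)
    dd <- sqrt(colSums((t(mesh@coords) - mesh@coords[center, ])^2))
    region <- which(dd <= cfg$injection$regionRadiusMm)
    if (!length(region)) stop("injection region empty")
    win <- which(tm >= cfg$injection$windowMs[1] &
                 tm <= cfg$injection$windowMs[2])
    if (inject && cfg$injection$effectSize > 0) {
      if (is.null(trueMetric)) stop("trueMetric needed for a nonzero injection")
      m <- as.numeric(trueMetric[ids])
      if (anyNA(m)) stop("trueMetric must cover every stimulus id")
      rng <- range(m)
      theta <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) * (pi / 2)
               else rep(pi / 4, n)
    } else theta <- rep(NA_real_, n)
    ## orthogonal mean-zero patterns with unit per-feature RMS: effectSize
    ## is the per-sample signal-to-noise ratio relative to noiseSd = 1, and
    ## mean-centering makes the Pearson distance between noiseless injected
    ## trials exactly 1 - cos(delta theta)
    nF <- length(region) * length(win)
    a <- rnorm(nF); a <- a - mean(a)
    u1 <- a / sqrt(sum(a^2)) * sqrt(nF)
    b <- rnorm(nF); b <- b - mean(b)
    b <- b - sum(b * u1) * u1 / nF
    u2 <- b / sqrt(sum(b^2)) * sqrt(nF)
    bg <- cfg$backgroundSd *
      outer(rnorm(nV), scale(cumsum(rnorm(nT)))[, 1])
    epochs <- vector("list", cfg$nSubjects)
    for (s in seq_len(cfg$nSubjects)) {
      X <- array(rnorm(n * nV * nT, 0, cfg$noiseSd), c(n, nV, nT))
      for (tr in seq_len(n)) X[tr, , ] <- X[tr, , ] + bg
      if (inject && cfg$injection$effectSize > 0) {
        for (tr in seq_len(n)) {
          sig <- cfg$injection$effectSize *
            (cos(theta[tr]) * u1 + sin(theta[tr]) * u2)
          X[tr, region, win] <- X[tr, region, win] +
            matrix(sig, length(region), length(win))
        }
      }
      epochs[[s]] <- new("SourceEpochs",
                         subjectId = sprintf("sub%02d", s), data = X,
                         timeMs = tm, epochName = epochName, trialIds = ids)
    }
    list(epochs = epochs, mesh = mesh,
         truth = list(regionVertices = region, windowSamples = win,
                      windowMs = cfg$injection$windowMs, theta = theta,
                      metric = trueMetric, epochName = epochName))
  })
}

#' Generate a complete synthetic analysis dataset
#'
#' Runs the whole generative pipeline: stimuli, block corpus, LMI
#' weighting, topic-model training for both slices, completion responses
#' for both stages, the three semantic blends, dispersion weights, the
#' four metric tables (three entropy models and the mismatch model), and
#' source epochs for all three alignment points with the configured
#' injection in its target epoch. Heard complement nouns for CN-bearing
#' stimuli are drawn from the stimulus's own sharpened constraint so the
#' mismatch metric varies meaningfully across trials.
#'
#' @param cfg a \code{\link{generatorConfig}} (use small \code{nTopics},
#'   \code{nVertices} and \code{nStimuli} for desk-scale work).
#' @param epochs which alignment points to simulate epochs for.
#' @return a bundle list: \code{stimuli}, \code{corpus}, \code{models},
#'   \code{dispersion}, \code{completions}, \code{blends},
#'   \code{metricTables}, \code{mesh}, \code{epochs} (per alignment
#'   point), \code{truth}
#' @export
simulateDataset <- function(cfg, epochs = c("SN_onset", "verb_onset",
                                            "CN_onset")) {
  stimuli <- makeStimuli(cfg)
  corpus <- makeCorpus(cfg)
  m1 <- trainTopicModel(computeLMI(corpus$sn_v), nTopics = cfg$nTopics,
                        nIter = cfg$lda$nIter, seed = cfg$seed,
                        weightScale = cfg$lda$weightScale)
  m2 <- trainTopicModel(computeLMI(corpus$snv_cn), nTopics = cfg$nTopics,
                        nIter = cfg$lda$nIter, seed = cfg$seed + 1,
                        weightScale = cfg$lda$weightScale)
  comp <- simulateCompletions(cfg, stimuli, corpus)
  tally1 <- tallyResponses(comp$responses[comp$responses$stage == "SNP", ],
                           stage = "SNP")
  tally2 <- tallyResponses(comp$responses[comp$responses$stage == "SNP_VERB", ],
                           stage = "SNP_VERB")

  lk1 <- topicDistributionMatrix(m1, colnames(m1@topicTarget), "target")
  lk2ctx <- m2@contextTopic
  lk2tgt <- topicDistributionMatrix(m2, colnames(m2@topicTarget), "target")

  blendOf <- function(tally, lookup, modelName) {
    out <- list()
    for (cs in tally) {
      if (!cs@included) next
      out[[cs@stimulusId]] <- makeBlend(completionDistribution(cs), lookup,
                                        modelName, cs@stimulusId)
    }
    out
  }
  blends <- list(
    SNP_to_verbs = blendOf(tally1, lk1, "SNP_to_verbs"),
    SNP_to_CNs = blendOf(tally1, lk2ctx, "SNP_to_CNs"),
    SNPverb_to_CNs = blendOf(tally2, lk2tgt, "SNPverb_to_CNs"))

  disp1 <- topicDispersion(m1, topK = min(20, ncol(m1@topicTarget)))
  disp2 <- topicDispersion(m2, topK = min(20, ncol(m2@topicTarget)))

  ## heard CN: drawn from the sharpened latent constraint, so the mismatch
  ## with the predicted blend varies across stimuli
  stimuli$cn_word <- NA_character_
  .withSeed(cfg$seed * 17 + 6, {
    for (i in which(stimuli$has_cn)) {
      p <- comp$truth$q2[i, corpus$latent$topicOfCN] /
        tabulate(corpus$latent$topicOfCN, cfg$nTopics)[corpus$latent$topicOfCN]
      stimuli$cn_word[i] <- sample(corpus$latent$cns, 1, prob = p / sum(p))
    }
  })
  targetDists <- list()
  for (i in which(stimuli$has_cn))
    targetDists[[stimuli$stimulus_id[i]]] <-
      wordTopicDistribution(m2, stimuli$cn_word[i], "target")

  metricTables <- list(
    SNP_to_verbs = buildMetricTable(stimuli, blends$SNP_to_verbs,
                                    "entropy", "SNP_to_verbs", disp1),
    SNP_to_CNs = buildMetricTable(stimuli, blends$SNP_to_CNs,
                                  "entropy", "SNP_to_CNs", disp2),
    SNPverb_to_CNs = buildMetricTable(stimuli, blends$SNPverb_to_CNs,
                                      "entropy", "SNPverb_to_CNs", disp2),
    mismatch_CN = buildMetricTable(stimuli, blends$SNPverb_to_CNs,
                                   "mismatch", "mismatch_CN",
                                   targetDists = targetDists))

  tgt <- cfg$injection$targetModelName
  mt <- metricTables[[tgt]]
  trueMetric <- setNames(mt$value, mt$stimulus_id)
  mesh <- simulateMesh(cfg)
  ep <- list()
  truths <- list()
  for (e in epochs) {
    sim <- simulateSourceEpochs(cfg, stimuli, trueMetric, mesh, e,
                                inject = (e == cfg$injection$epochName))
    ep[[e]] <- sim$epochs
    truths[[e]] <- sim$truth
  }
  list(stimuli = stimuli, corpus = corpus, models = list(sn_v = m1, snv_cn = m2),
       dispersion = list(sn_v = disp1, snv_cn = disp2),
       completions = list(stage1 = tally1, stage2 = tally2, truth = comp$truth),
       blends = blends, metricTables = metricTables, mesh = mesh,
       epochs = ep, truth = truths, config = cfg)
}
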