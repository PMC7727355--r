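test_that("stimulus tables reproduce the design structure deterministically", {
  cfg <- generatorConfig(seed = 2)
  stim <- makeStimuli(cfg)
  expect_equal(nrow(stim), 200)
  expect_equal(length(unique(stim$rep_group)), 50)   # groups of 4
  expect_true(all(table(stim$rep_group) == 4))
  ## SNP + verb shared within a repetition group
  expect_true(all(tapply(stim$verb_word, stim$rep_group,
                         function(x) length(unique(x))) == 1))
  ## CN-bearing share close to the modeled 128/200
  expect_lt(abs(sum(stim$has_cn) - 128), 10 + 1)
  ## onsets ordered, uniqueness points inside the words
  expect_true(all(stim$verb_onset_ms > stim$sn_onset_ms))
  expect_true(all(stim$cn_onset_ms > stim$verb_onset_ms))
  expect_true(all(stim$sn_up_ms > stim$sn_onset_ms))

  expect_identical(stim, makeStimuli(generatorConfig(seed = 2)))
  expect_false(identical(stim, makeStimuli(generatorConfig(seed = 3))))
})

test_that("block corpora are identifiable and scale-stable", {
  cfg <- generatorConfig(seed = 6, nTopics = 3,
                         corpus = list(contextsPerTopic = 3,
                                       targetsPerTopic = 5, noiseRate = 0))
  corpus <- makeCorpus(cfg)
  cnt <- cooccurrenceCounts(corpus$sn_v)
  same <- outer(corpus$latent$topicOfSN, corpus$latent$topicOfVerb, "==")
  expect_true(all(cnt[!same] == 0))            # separable blocks
  expect_gt(mean(cnt[same]), 10)
  expect_identical(cooccurrenceCounts(makeCorpus(cfg)$sn_v), cnt)

  ## doubling the within-block rate leaves the normalized block structure
  ## unchanged in expectation
  cfg2 <- generatorConfig(seed = 6, nTopics = 3,
                          corpus = list(contextsPerTopic = 3,
                                        targetsPerTopic = 5,
                                        withinRate = 40, noiseRate = 0))
  n1 <- rowSums(cnt > 0) / ncol(cnt)
  n2 <- rowSums(cooccurrenceCounts(makeCorpus(cfg2)$sn_v) > 0) / ncol(cnt)
  expect_equal(mean(n1), mean(n2), tolerance = 0.05)
})

test_that("completion responses encode a sharpened stage-2 constraint", {
  cfg <- generatorConfig(seed = 9, nStimuli = 60, nTopics = 4,
                         stage2Sharpening = 8)
  corpus <- makeCorpus(cfg)
  stim <- makeStimuli(cfg)
  comp <- simulateCompletions(cfg, stim, corpus)
  ## strong sharpening: latent stage-2 entropy far below stage-1
  expect_lt(mean(comp$truth$entropy2), mean(comp$truth$entropy1))

  ## sharpening = 1 leaves the latent distribution untouched (null control)
  cfg1 <- generatorConfig(seed = 9, nStimuli = 60, nTopics = 4,
                          stage2Sharpening = 1)
  comp1 <- simulateCompletions(cfg1, stim, corpus)
  expect_equal(comp1$truth$q1, comp1$truth$q2)

  ## response counts match the study sizes
  agg <- tapply(comp$responses$count[comp$responses$stage == "SNP"],
                comp$responses$stimulus_id[comp$responses$stage == "SNP"], sum)
  expect_true(all(agg == cfg$stage1N))

  ## a stimulus given < 4 responses is excluded downstream
  cfgS <- generatorConfig(seed = 9, nStimuli = 60, nTopics = 4, stage2N = 3)
  compS <- simulateCompletions(cfgS, stim, corpus)
  tallyS <- tallyResponses(compS$responses[compS$responses$stage == "SNP_VERB", ],
                           "SNP_VERB")
  expect_true(all(!vapply(tallyS, isIncluded, logical(1))))
})

test_that("the injected angular code makes the model RDM recoverable", {
  ## near-noiseless injection: data RDM at an injected center must rank
  ## exactly like the absolute metric differences
  cfg <- generatorConfig(seed = 13, nStimuli = 20, nSubjects = 1,
                         nVertices = 20, samplingRate = 50,
                         noiseSd = 1e-4, backgroundSd = 0,
                         injection = list(effectSize = 5))
  stim <- makeStimuli(cfg)
  set.seed(13)
  met <- setNames(rnorm(20), stim$stimulus_id)
  sim <- simulateSourceEpochs(cfg, stim, met)
  ## the full injected region x window: the patterns are mean-zero over
  ## exactly this feature set
  mem <- cbind(vertex = rep(sim$truth$regionVertices,
                            times = length(sim$truth$windowSamples)),
               timeIdx = rep(sim$truth$windowSamples,
                             each = length(sim$truth$regionVertices)))
  d <- dataRDM(sim$epochs[[1]], mem)
  rho <- cor(rdmVector(d), rdmVector(modelRDM(met)), method = "spearman")
  expect_gt(rho, 0.99)

  ## trials with equal metric values get identical patterns up to noise
  met2 <- met
  met2[2] <- met2[1]
  sim2 <- simulateSourceEpochs(cfg, stim, met2)
  d2 <- rdmMatrix(dataRDM(sim2$epochs[[1]], mem))
  expect_lt(d2[1, 2], 1e-4)

  ## full determinism under the seed
  sim3 <- simulateSourceEpochs(cfg, stim, met)
  expect_identical(epochData(sim3$epochs[[1]]), epochData(sim$epochs[[1]]))
})

test_that("generated artifacts round-trip through the plain-text readers", {
  cfg <- generatorConfig(seed = 4, nStimuli = 8, nSubjects = 2,
                         nVertices = 10, samplingRate = 25, nTopics = 2,
                         corpus = list(contextsPerTopic = 2,
                                       targetsPerTopic = 3))
  stim <- makeStimuli(cfg)
  sim <- simulateSourceEpochs(cfg, stim, setNames(rnorm(8), stim$stimulus_id))
  dir <- file.path(tempdir(), "bundle-roundtrip")
  writeEpochsBundle(sim$epochs, sim$mesh, dir)
  back <- readEpochsBundle(dir)
  expect_identical(meshCoords(back$mesh), meshCoords(sim$mesh))
  expect_identical(back$epochs[[1]]@data, sim$epochs[[1]]@data)
  expect_identical(back$epochs[[2]]@trialIds, sim$epochs[[2]]@trialIds)

  corpus <- makeCorpus(cfg)
  model <- trainTopicModel(computeLMI(corpus$sn_v), nTopics = 2,
                           nIter = 50, seed = 3)
  mdir <- file.path(tempdir(), "model-roundtrip")
  writeTopicModel(model, mdir)
  back2 <- readTopicModel(mdir)
  expect_identical(contextTopic(back2), contextTopic(model))
  expect_identical(topicTarget(back2), topicTarget(model))
  expect_identical(topicPrior(back2), topicPrior(model))

  r <- rand_rdm(5, "data")
  rpath <- file.path(tempdir(), "rdm.tsv")
  writeRDM(r, rpath)
  expect_identical(rdmMatrix(readRDM(rpath)), rdmMatrix(r))
})
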