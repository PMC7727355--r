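test_that("partial Spearman reduces to classical Spearman and handles edge cases", {
  set.seed(21)
  a <- rand_rdm(6, "data")
  expect_equal(partialSpearman(a, a), 1)

  for (i in 1:20) {
    d <- rand_rdm(6, "data"); m <- rand_rdm(6, "model")
    expect_equal(partialSpearman(d, m),
                 cor(rdmVector(d), rdmVector(m), method = "spearman"),
                 tolerance = 1e-10)
  }

  ## covariate identical to the model: fit defined as 0 with a warning
  d <- rand_rdm(6, "data"); m <- rand_rdm(6, "model")
  expect_warning(fit <- partialSpearman(d, m, list(m)), "zero residual")
  expect_equal(fit, 0)

  ## too few triangle entries for the covariate count
  tiny <- rand_rdm(3, "data")
  covs <- replicate(3, rand_rdm(3, "covariate"))
  expect_error(partialSpearman(tiny, rand_rdm(3, "model"), covs),
               "fewer RDM triangle entries")

  ## label alignment: permuting one RDM's labels must not change the fit
  d5 <- rand_rdm(5, "data"); m5 <- rand_rdm(5, "model")
  perm <- sample(5)
  m5p <- new("RDM", labels = m5@labels[perm],
             d = m5@d[perm, perm], kind = "model")
  expect_equal(partialSpearman(d5, m5), partialSpearman(d5, m5p))
})

test_that("subject fit maps match the per-center reference path", {
  set.seed(77)
  cfg <- generatorConfig(seed = 77, nStimuli = 12, nSubjects = 2,
                         nVertices = 15, samplingRate = 100)
  stim <- makeStimuli(cfg)
  met <- setNames(rnorm(12), stim$stimulus_id)
  sim <- simulateSourceEpochs(cfg, stim, met)
  idx <- buildSearchlightIndex(sim$mesh, sim$epochs[[1]]@timeMs)
  mrdm <- modelRDM(met)
  cov <- covariateRDMs(stim, "verb_onset", labels = mrdm@labels)
  maps <- subjectFitMaps(sim$epochs, idx, mrdm, cov)
  f <- fitMaps(maps)
  for (v in c(1, 8, 15)) for (ti in c(1, 31, 61)) {
    mem <- searchlightMembers(idx, v, ti)
    ref <- partialSpearman(dataRDM(sim$epochs[[2]], mem), mrdm, cov)
    expect_equal(f[2, v, ti], ref, tolerance = 1e-8)
  }

  ## a duplicated subject produces an identical map
  maps2 <- subjectFitMaps(list(sim$epochs[[1]], sim$epochs[[1]]), idx,
                          mrdm, cov)
  expect_identical(fitMaps(maps2)[1, , ], fitMaps(maps2)[2, , ])

  ## a subject missing most trials is excluded with a warning
  short <- sim$epochs[[1]]
  short@data <- short@data[1:5, , , drop = FALSE]
  short@trialIds <- short@trialIds[1:5]
  expect_warning(maps3 <- subjectFitMaps(list(sim$epochs[[1]], short), idx,
                                         mrdm, cov),
                 "missing more than 50%")
  expect_equal(dim(fitMaps(maps3))[1], 1)
})

test_that("pure-noise fit maps are centred on zero", {
  cfg <- generatorConfig(seed = 5, nStimuli = 20, nSubjects = 4,
                         nVertices = 30, samplingRate = 50,
                         injection = list(effectSize = 0))
  stim <- makeStimuli(cfg)
  sim <- simulateSourceEpochs(cfg, stim, inject = FALSE)
  idx <- buildSearchlightIndex(sim$mesh, sim$epochs[[1]]@timeMs)
  set.seed(55)
  met <- setNames(seq_len(20) + rnorm(20), stim$stimulus_id)
  mrdm <- modelRDM(met)
  maps <- subjectFitMaps(sim$epochs, idx, mrdm)
  f <- fitMaps(maps)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f)), 3 * max(se, 1e-3))
})

test_that("group t-maps implement the one-sample t with df = n - 1", {
  fits <- array(0, c(4, 2, 3))
  vals <- c(0.5, 0.52, 0.48, 0.5)
  for (s in 1:4) fits[s, , ] <- vals[s]
  maps <- new("SearchlightMap", modelName = "m", fits = fits,
              subjectIds = paste0("sub", 1:4),
              timeMs = c(0, 300, 600))
  tm <- groupTMap(maps)
  expect_equal(tm@df, 3L)
  expect_equal(tValues(tm)[1, 1],
               mean(vals) / (sd(vals) / sqrt(4)), tolerance = 1e-12)

  ## symmetric +/- pairs: t = 0
  fits2 <- fits
  fits2[, 1, 1] <- c(0.3, -0.3, 0.1, -0.1)
  maps2 <- new("SearchlightMap", modelName = "m", fits = fits2,
               subjectIds = paste0("sub", 1:4), timeMs = c(0, 300, 600))
  expect_equal(tValues(groupTMap(maps2))[1, 1], 0)

  ## zero across-subject variance: flagged missing
  fits3 <- fits
  fits3[, 2, 1] <- 0.4
  maps3 <- new("SearchlightMap", modelName = "m", fits = fits3,
               subjectIds = paste0("sub", 1:4), timeMs = c(0, 300, 600))
  expect_true(is.na(tValues(groupTMap(maps3))[2, 1]))

  ## 13 subjects give df = 12
  fits13 <- array(rnorm(13 * 2 * 3, 0.2, 0.1), c(13, 2, 3))
  maps13 <- new("SearchlightMap", modelName = "m", fits = pmin(pmax(fits13, -1), 1),
                subjectIds = paste0("sub", 1:13), timeMs = c(0, 300, 600))
  expect_equal(groupTMap(maps13)@df, 12L)
})

test_that("cluster forming groups contiguous supra-threshold points", {
  ## single vertex, 4 samples, t = [3, 3, 0, 3], threshold 2.5:
  ## two clusters with masses 6 and 3
  mesh <- line_mesh(1)
  tmat <- matrix(c(3, 3, 0, 3), 1, 4)
  tm <- new("TMap", t = tmat, df = 12L, tail = "positive")
  ## choose cftP so the Student-t threshold lands at ~2.5
  cft <- 1 - pt(2.5, df = 12)
  cl <- formClusters(tm, mesh, cftP = cft + 1e-12)
  expect_length(cl, 2)
  expect_equal(sapply(cl, `[[`, "mass"), c(6, 3))

  ## two supra vertices never adjacent: separate clusters
  mesh2 <- line_mesh(3)   # chain 1-2-3
  tmat2 <- rbind(c(3, 0), c(0, 0), c(3, 0))
  tm2 <- new("TMap", t = tmat2, df = 12L, tail = "positive")
  cl2 <- formClusters(tm2, mesh2, cftP = cft)
  expect_length(cl2, 2)

  expect_error(formClusters(tm, mesh, cftP = 0.7), "cftP")
  ## nothing supra-threshold: empty list is valid
  tm3 <- new("TMap", t = matrix(0, 1, 4), df = 12L, tail = "positive")
  expect_length(formClusters(tm3, mesh, cftP = 0.01), 0)
})

test_that("sign-flip permutation p-values follow the add-one counting rule", {
  set.seed(3)
  fits <- array(rnorm(6 * 8 * 10, 0.12, 0.2), c(6, 8, 10))
  maps <- new("SearchlightMap", modelName = "m",
              fits = pmin(pmax(fits, -1), 1),
              subjectIds = paste0("sub", 1:6),
              timeMs = seq(0, 600, length.out = 10))
  mesh <- line_mesh(8)
  res <- signFlipPermutation(maps, mesh, cftP = 0.05, nPerm = 99, seed = 11)
  expect_length(res@nullMaxMasses, 99)
  for (cl in clusters(res)) {
    expect_equal(cl$p, (1 + sum(res@nullMaxMasses >= cl$mass)) / 100)
    expect_gte(cl$p, 1 / 100)          # never exactly zero
  }

  ## seeded determinism of the null
  res2 <- signFlipPermutation(maps, mesh, cftP = 0.05, nPerm = 99, seed = 11)
  expect_identical(res@nullMaxMasses, res2@nullMaxMasses)

  ## subject exchangeability: permuting subjects leaves everything invariant
  perm <- c(4, 1, 6, 2, 5, 3)
  mapsP <- new("SearchlightMap", modelName = "m",
               fits = maps@fits[perm, , ], subjectIds = maps@subjectIds[perm],
               timeMs = maps@timeMs)
  expect_equal(tValues(groupTMap(mapsP)), tValues(groupTMap(maps)))

  ## fewer than 5 subjects: warn about the narrow sign-flip support
  maps4 <- new("SearchlightMap", modelName = "m",
               fits = maps@fits[1:4, , ], subjectIds = maps@subjectIds[1:4],
               timeMs = maps@timeMs)
  expect_warning(signFlipPermutation(maps4, mesh, nPerm = 20, seed = 1),
                 "sign-flip null")
})

test_that("cluster reports tier clusters at the 0.05 / 0.06 cuts", {
  mk <- function(p, mass = 10)
    list(members = cbind(vertex = 1:2, timeIdx = c(3, 4)), mass = mass, p = p)
  res <- new("ClusterResult",
             clusters = list(mk(0.032), mk(0.058), mk(0.2)),
             cftP = 0.01, tThreshold = 2.681, nPerm = 1000L,
             nullMaxMasses = rep(1, 1000), seed = 1L, df = 12L,
             timeMs = seq(0, 600, by = 100))
  rep_ <- reportClusters(res)
  expect_equal(rep_$tier, c("significant", "marginal", "ns"))
  expect_equal(rep_$onset_ms[1], 200)
  expect_equal(rep_$offset_ms[1], 300)
  expect_equal(rep_$n_vertices[1], 2)
})
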