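test_that("LMI weighting follows the clamped n*log(n N / (r c)) rule", {
  m <- matrix(c(10, 0, 0, 10), 2, 2,
              dimnames = list(c("c1", "c2"), c("t1", "t2")))
  w <- lmiWeights(computeLMI(cooccurrenceTable(m, "SN_V")))
  expect_equal(unname(diag(w)), rep(10 * log(2), 2))
  expect_equal(w[1, 2], 0)
  expect_equal(w[2, 1], 0)

  ## perfect independence: every PMI is 0
  m2 <- matrix(5, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_true(all(lmiWeights(computeLMI(cooccurrenceTable(m2, "SN_V"))) == 0))

  ## negative PMI clamps to 0: cell (1,1) under-represented
  m3 <- matrix(c(1, 9, 9, 1), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  w3 <- lmiWeights(computeLMI(cooccurrenceTable(m3, "SN_V")))
  expect_equal(w3[1, 1], 0)
  expect_gt(w3[2, 1], 0)

  empty <- cooccurrenceTable(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))), "SN_V")
  expect_error(computeLMI(empty), "empty co-occurrence table")
})

test_that("LMI of any rank-one (independent) table is identically zero", {
  set.seed(42)
  for (i in 1:20) {
    r <- rgamma(4, 2); cs <- rgamma(5, 2)
    m <- outer(r, cs) / sum(r)   # counts factorize exactly
    dimnames(m) <- list(paste0("c", 1:4), paste0("t", 1:5))
    w <- lmiWeights(computeLMI(cooccurrenceTable(m, "SN_V")))
    expect_lt(max(abs(w)), 1e-8)
  }
})

test_that("topic model training is seeded-deterministic and recovers blocks", {
  cfg <- generatorConfig(seed = 5, nStimuli = 8, nTopics = 2,
                         corpus = list(contextsPerTopic = 3,
                                       targetsPerTopic = 4, noiseRate = 0))
  corpus <- makeCorpus(cfg)
  wt <- computeLMI(corpus$sn_v)
  m <- trainTopicModel(wt, nTopics = 2, nIter = 200, seed = 7)
  m_again <- trainTopicModel(wt, nTopics = 2, nIter = 200, seed = 7)
  expect_identical(contextTopic(m), contextTopic(m_again))
  expect_identical(topicTarget(m), topicTarget(m_again))

  ## each block's contexts concentrate on one topic, permutation-invariant
  assigned <- apply(contextTopic(m), 1, which.max)
  truth <- corpus$latent$topicOfSN
  expect_gte(topic_purity(assigned, truth), 0.9)

  ## simplex invariants
  expect_lt(max(abs(rowSums(contextTopic(m)) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(topicTarget(m)) - 1)), 1e-9)
  expect_true(all(topicPrior(m) > 0))
})

test_that("degenerate and invalid training configurations are handled", {
  m <- matrix(c(10, 2, 3, 9), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  wt <- computeLMI(cooccurrenceTable(m, "SN_V"))
  one <- trainTopicModel(wt, nTopics = 1, nIter = 50, seed = 1)
  expect_equal(unname(contextTopic(one)[, 1]), rep(1, nrow(contextTopic(one))))
  expect_error(trainTopicModel(wt, nTopics = 5, nIter = 10, seed = 1),
               "exceeds the number of distinct targets")

  ## a context word with all-zero weights is excluded with a warning
  m2 <- matrix(c(10, 5, 5, 10, 0, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "z"), c("x", "y")))
  wt2 <- computeLMI(cooccurrenceTable(m2, "SN_V"))
  expect_warning(m2f <- trainTopicModel(wt2, nTopics = 2, nIter = 50, seed = 1),
                 "all-zero weights")
  expect_false("z" %in% rownames(contextTopic(m2f)))
})

test_that("word topic distributions: direct lookup and Bayes inversion", {
  ct <- rbind(walker = c(0.7, 0.3), court = c(0.2, 0.8))
  tt <- rbind(c(0.2, 0.8), c(0.0, 1.0))
  colnames(tt) <- c("w", "v")
  model <- new("TopicModel", sliceName = "SN_V", nTopics = 2L,
               contextTopic = ct, topicTarget = tt,
               topicPrior = c(0.5, 0.5), trainingConfig = list())
  expect_equal(probs(wordTopicDistribution(model, "walker", "context")),
               c(0.7, 0.3))
  ## P(topic|w) with column (0.2, 0.0) and uniform prior -> (1, 0)
  expect_equal(probs(wordTopicDistribution(model, "w", "target")), c(1, 0))
  expect_error(wordTopicDistribution(model, "nope", "context"),
               "'nope' not in the context vocabulary")
  expect_error(wordTopicDistribution(model, "walker", "target"),
               "'walker' not in the target vocabulary")
})
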