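test_that("blends are probability-weighted mixtures with OOV renormalization", {
  lk <- rbind(a = c(0.8, 0.2), b = c(0.4, 0.6))
  b <- makeBlend(c(A = 0.75, B = 0.25), lk, "SNP_to_verbs", "s1")
  expect_equal(probs(b), c(0.7, 0.3))

  ## single word: blend equals that word's distribution
  expect_equal(probs(makeBlend(c(a = 1), lk, "m", "s")), c(0.8, 0.2))

  ## mixture of identical distributions is that distribution
  lk2 <- rbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  expect_equal(probs(makeBlend(c(a = 0.6, b = 0.4), lk2, "m", "s")),
               c(0.3, 0.7))

  ## OOV words dropped, weights renormalized
  b3 <- makeBlend(c(a = 0.5, zz = 0.5), lk, "m", "s")
  expect_equal(probs(b3), c(0.8, 0.2))
  expect_equal(b3@contributingWords, c(a = 1))
  expect_error(makeBlend(c(zz = 1), lk, "m", "s"), "no resolvable candidates")
})

test_that("dispersion weights average pairwise cosine distances per topic", {
  ## both topics emit the same word distribution -> every word's inverted
  ## distribution equals the prior -> zero dispersion everywhere
  tt <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  colnames(tt) <- c("x", "y", "z")
  same <- new("TopicModel", sliceName = "SNV_CN", nTopics = 2L,
              contextTopic = matrix(c(0.5, 0.5), 1,
                                    dimnames = list("c1", NULL)),
              topicTarget = tt, topicPrior = c(0.4, 0.6),
              trainingConfig = list())
  expect_equal(topicDispersion(same, topK = 3)@w, c(0, 0))

  ## random model: agrees with direct enumeration over word pairs
  set.seed(31)
  K <- 4; V <- 9
  tt <- t(sapply(seq_len(K), function(i) rand_simplex(V)))
  colnames(tt) <- paste0("w", seq_len(V))
  prior <- rand_simplex(K)
  model <- new("TopicModel", sliceName = "SNV_CN", nTopics = as.integer(K),
               contextTopic = matrix(rand_simplex(K), 1,
                                     dimnames = list("c1", NULL)),
               topicTarget = tt, topicPrior = prior,
               trainingConfig = list())
  topK <- 5
  dw <- topicDispersion(model, topK = topK)
  for (k in seq_len(K)) {
    top <- names(sort(tt[k, ], decreasing = TRUE))[seq_len(topK)]
    dists <- sapply(top, function(w)
      probs(wordTopicDistribution(model, w, "target")))
    pairs <- combn(topK, 2)
    cosd <- apply(pairs, 2, function(ij) {
      a <- dists[, ij[1]]; b <- dists[, ij[2]]
      1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    })
    expect_equal(dw@w[k], mean(cosd), tolerance = 1e-12)
  }

  ## mean of an enumerated pair set: distances {0.2, 0.4, 0.6} -> 0.4
  expect_equal(mean(c(0.2, 0.4, 0.6)), 0.4)
  expect_error(topicDispersion(model, topK = 1), "topK must be >= 2")
})

test_that("weighted entropy matches closed forms and Shannon entropy", {
  expect_equal(weightedEntropy(rep(1 / 100, 100), rep(1, 100)), log(100),
               tolerance = 1e-12)
  expect_equal(weightedEntropy(c(1, rep(0, 9)), runif(10)), 0)
  expect_equal(weightedEntropy(c(0.5, 0.5, 0, 0), c(1, 0.5, 1, 1)),
               0.75 * log(2), tolerance = 1e-12)
  expect_error(weightedEntropy(c(0.5, 0.5), c(1, 1, 1)), "length mismatch")

  set.seed(4)
  for (i in 1:25) {
    p <- rand_simplex(sample(3:30, 1))
    shannon <- -sum(ifelse(p > 0, p * log(p), 0))
    expect_equal(weightedEntropy(p, rep(1, length(p))), shannon,
                 tolerance = 1e-12)
  }
})

test_that("unit-weight entropy is maximal at the uniform distribution", {
  set.seed(8)
  n <- 12
  hmax <- weightedEntropy(rep(1 / n, n), rep(1, n))
  for (i in 1:50)
    expect_lte(weightedEntropy(rand_simplex(n), rep(1, n)), hmax + 1e-12)
})

test_that("cosine mismatch has the right geometry", {
  v <- rand_simplex(6)
  expect_equal(cosineMismatch(v, v), 0, tolerance = 1e-12)
  expect_equal(cosineMismatch(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineMismatch(c(1, 0), c(0.5, 0.5)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosineMismatch(c(0, 0), c(1, 0)), "zero vector")
  set.seed(12)
  for (i in 1:20) {
    a <- rand_simplex(8); b <- rand_simplex(8)
    expect_equal(cosineMismatch(a, b), cosineMismatch(b, a))
    expect_gte(cosineMismatch(a, b), 0)
    expect_lte(cosineMismatch(a, b), 1 + 1e-12)  # non-negative vectors
  }
})

test_that("metric tables have one row per eligible stimulus", {
  stim <- data.frame(stimulus_id = paste0("s", 1:5),
                     has_cn = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  lk <- rbind(a = c(0.9, 0.1), b = c(0.2, 0.8))
  blends <- setNames(lapply(1:5, function(i)
    makeBlend(c(a = i / 6, b = 1 - i / 6), lk, "m", paste0("s", i))),
    paste0("s", 1:5))
  ent <- buildMetricTable(stim, blends, "entropy", "m")
  expect_equal(nrow(ent), 5)

  tds <- setNames(lapply(1:5, function(i)
    new("TopicDistribution", word = "w", probs = c(0.5, 0.5),
        source = "target")), paste0("s", 1:5))
  mis <- buildMetricTable(stim, blends, "mismatch", "mm", targetDists = tds)
  expect_equal(nrow(mis), 3)          # only the has_cn stimuli
  expect_true(all(mis$stimulus_id %in% c("s1", "s2", "s4")))

  ## values do not depend on stimulus order
  ent2 <- buildMetricTable(stim[5:1, ], blends, "entropy", "m")
  expect_equal(ent2$value[match(ent$stimulus_id, ent2$stimulus_id)],
               ent$value)

  ## missing blend: row dropped with a warning
  expect_warning(ent3 <- buildMetricTable(stim, blends[-2], "entropy", "m"),
                 "no blend")
  expect_equal(nrow(ent3), 4)
})
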