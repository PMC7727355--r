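test_that("model RDMs are absolute metric differences", {
  r <- modelRDM(c(t1 = 1, t2 = 3, t3 = 6))
  d <- rdmMatrix(r)
  expect_equal(sort(d[lower.tri(d)]), c(2, 3, 5))
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d, t(d))
  expect_error(modelRDM(c(a = 2, b = 2, c = 2)),
               "degenerate model RDM \\(zero variance\\)")
  expect_error(modelRDM(c(a = 1, b = 2)), "at least 3")

  ## positive affine transform scales distances and preserves ranks
  v <- c(a = 0.3, b = 1.2, c = 2.5, d = 0.9)
  d1 <- rdmVector(modelRDM(v))
  d2 <- rdmVector(modelRDM(3 * v + 10))
  expect_equal(d2, 3 * d1)
  expect_equal(rank(d1), rank(d2))
})

test_that("covariate RDMs encode alignment-word frequency and repetition", {
  stim <- data.frame(stimulus_id = paste0("s", 1:4),
                     rep_group = c("g1", "g1", "g2", "g2"),
                     verb_logfreq = c(1.0, 1.0, 0.5, 2.0))
  cov <- covariateRDMs(stim, "verb_onset")
  f <- rdmMatrix(cov$frequency)
  expect_equal(f[1, 2], 0)                  # equal frequency
  expect_equal(f[3, 4], 1.5)
  r <- rdmMatrix(cov$repetition)
  expect_equal(r[1, 2], 0)                  # same SNP+verb group
  expect_equal(r[1, 3], 1)
  expect_equal(sum(r[lower.tri(r)] == 0), 2)  # exactly the 2 within-group pairs

  expect_error(covariateRDMs(stim, "SN_onset"),
               "'sn_logfreq'")
})

test_that("searchlight membership respects both radii and epoch edges", {
  ## two clusters of vertices, one isolated vertex far away
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(8, 0, 0), c(60, 0, 0))
  mesh <- corticalMesh(coords, cbind(1:3, c(2, 3, 1)))
  tm <- seq(0, 600, by = 10)
  idx <- buildSearchlightIndex(mesh, tm, rMm = 10, rMs = 30)

  ## isolated vertex: spatial members are itself only
  m4 <- searchlightMembers(idx, 4, 31)
  expect_true(all(m4[, "vertex"] == 4))
  expect_equal(nrow(m4), 7)                 # +/- 3 samples at 100 Hz

  ## 1 kHz sampling: 61 samples per center away from the edges
  idx1k <- buildSearchlightIndex(mesh, seq(0, 600, by = 1), rMm = 10, rMs = 30)
  expect_equal(nrow(searchlightMembers(idx1k, 4, 300)), 61)
  ## epoch edge: truncated window, no wraparound
  expect_equal(nrow(searchlightMembers(idx1k, 4, 1)), 31)

  ## reflexive membership; smaller radius never adds members
  idx5 <- buildSearchlightIndex(mesh, tm, rMm = 5, rMs = 30)
  for (v in 1:4) {
    expect_true(v %in% idx@spatialMembers[[v]])
    expect_true(all(idx5@spatialMembers[[v]] %in% idx@spatialMembers[[v]]))
  }
  expect_error(buildSearchlightIndex(corticalMesh(matrix(0, 0, 3),
    matrix(integer(), 0, 2)), tm), "empty mesh")
})

test_that("data RDMs are 1 - Pearson with principled degenerate handling", {
  tm <- seq(0, 600, length.out = 4)
  base <- c(1, 2, 3, 1, 2, 3, 1, 2)     # 2 vertices x 4 samples
  X <- array(0, c(3, 2, 4))
  X[1, , ] <- base
  X[2, , ] <- 2 * base + 5              # positive affine: distance 0
  X[3, , ] <- -base                     # negation: distance 2
  ep <- epochs_from_array(X, timeMs = tm)
  members <- cbind(vertex = rep(1:2, 4), timeIdx = rep(1:4, each = 2))
  d <- rdmMatrix(dataRDM(ep, members))
  expect_equal(d[1, 2], 0, tolerance = 1e-12)
  expect_equal(d[1, 3], 2, tolerance = 1e-12)
  expect_equal(diag(d), rep(0, 3))

  ## hand Pearson: [1,2,3] vs [1,2,4]
  Y <- array(1, c(3, 1, 3))
  Y[1, 1, ] <- c(1, 2, 3)
  Y[2, 1, ] <- c(1, 2, 4)
  Y[3, 1, ] <- c(3, 1, 2)
  ep2 <- epochs_from_array(Y, timeMs = c(0, 300, 600))
  d2 <- rdmMatrix(dataRDM(ep2, cbind(vertex = 1, timeIdx = 1:3)))
  expect_equal(d2[1, 2], 1 - cor(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)

  ## zero-variance trial vector: its pairs get the maximal distance 1
  Z <- Y
  Z[3, 1, ] <- 7
  expect_warning(d3 <- rdmMatrix(dataRDM(epochs_from_array(Z,
    timeMs = c(0, 300, 600)), cbind(vertex = 1, timeIdx = 1:3))),
    "zero variance")
  expect_equal(d3[1, 3], 1)
  expect_equal(d3[2, 3], 1)
  expect_error(dataRDM(ep2, cbind(vertex = 1, timeIdx = 1)),
               "at least 2 member points")
})
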