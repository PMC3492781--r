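# Synthetic study generator: networks, layouts, forward simulation.

test_that("simulation config validates its inputs", {
  expect_error(
    simConfig("A", sampleSizes = c(A = 10L), migrationScale = 1.5),
    "probabilities"
  )
  expect_error(
    simConfig("A", sampleSizes = c(A = 500L), demeSize = 100L),
    "exceeds deme size"
  )
  expect_error(
    simConfig(c("A", "B"),
      siteCluster = c(s1 = "A", s2 = "C"),
      sampleSizes = c(s1 = 5L, s2 = 5L)
    ),
    "unknown deme"
  )
  expect_error(
    simConfig("A", sampleSizes = c(A = 10L), outlierDeme = "Z"),
    "outlierDeme"
  )
  expect_error(
    simConfig("A", sampleSizes = c(A = 10L), multistepVariance = 0),
    "multistepVariance"
  )
})

test_that("config YAML round trip preserves every field", {
  cfg <- studyConfig(outlier = TRUE, seed = 9L)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeSimConfig(cfg, f)
  back <- readSimConfig(f)
  expect_equal(back[order(names(back))], cfg[order(names(cfg))])
})

test_that("vector networks obey total, symmetry and determinism", {
  expect_error(generateVectorNetwork("A", 100), "at least 2")
  w <- generateVectorNetwork(LETTERS[1:8], totalTransits = 32000, seed = 4)
  expect_equal(sum(w[row(w) != col(w)]), 32000)
  expect_equal(unname(diag(w)), rep(0, 8))
  sym <- generateVectorNetwork(LETTERS[1:5], 500, asymmetry = 0, seed = 6)
  expect_equal(sym, t(sym))
  expect_identical(
    generateVectorNetwork(LETTERS[1:6], 1000, seed = 11),
    generateVectorNetwork(LETTERS[1:6], 1000, seed = 11)
  )
})

test_that("dominant-corridor networks dominate their recipient columns", {
  w <- dominantEdgeNetwork(LETTERS[1:8], nStrong = 3, dominance = 2.5, seed = 2)
  se <- attr(w, "strongEdges")
  expect_equal(nrow(se), 3L)
  for (s in seq_len(3)) {
    i <- se[s, 1]
    j <- se[s, 2]
    expect_gte(w[i, j] / (sum(w[, j]) - w[i, j]), 2.5 - 1e-9)
  }
})

test_that("coastline distances are absolute differences", {
  d <- distanceMatrixFromLayout(c(a = 0, b = 3, c = 10))
  expect_equal(d["a", "c"], 10)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  flat <- distanceMatrixFromLayout(c(a = 2, b = 2, c = 2))
  expect_true(all(flat == 0))
  expect_error(
    distanceMatrixFromLayout(setNames(c(1, 2), c("a", "a"))),
    "duplicate"
  )
})

test_that("identical config and seed reproduce the panel bit for bit", {
  w <- generateVectorNetwork(studyDesign()$demes, seed = 31)
  cfg <- studyConfig(outlier = TRUE, seed = 32)
  p1 <- simulatePanel(cfg, w)
  p2 <- simulatePanel(cfg, w)
  expect_identical(p1@alleleA, p2@alleleA)
  expect_identical(p1@alleleB, p2@alleleB)
  expect_identical(sites(p1), sites(p2))
})

test_that("isolated demes with distinct pools exceed within-deme differentiation", {
  # m = 0, divergent founders: between-deme theta far above the
  # within-deme (two samples of one deme) level
  between <- pairwiseFst(twoDemePanel(seed = 41, divergence = 0.6))["X", "Y"]
  cfg <- simConfig("X",
    sampleSizes = c(u = 30L, v = 30L), siteCluster = c(u = "X", v = "X"),
    migrationScale = 0, missingRate = 0, seed = 42
  )
  pan <- simulatePanel(cfg, generateVectorNetwork(c("X", "Z"), seed = 43))
  clusters(pan) <- sites(pan)
  within <- pairwiseFst(pan)["u", "v"]
  expect_gt(between, within + 0.05)
})

test_that("drift alone loses heterozygosity at rate 1/(2N)", {
  # m = 0, mu = 0, no selfing: E[H_t] = H_0 (1 - 1/(2N))^t
  N <- 50L
  gens <- 10L
  reps <- 40
  h <- replicate(reps, {
    cfg <- simConfig("X",
      sampleSizes = c(X = N), demeSize = N, founderSize = N,
      generations = gens, migrationScale = 0, mutationRate = 0,
      selfingRate = 0, founderDivergence = 0, missingRate = 0,
      seed = sample.int(1e6, 1)
    )
    pan <- simulatePanel(cfg, generateVectorNetwork(c("X", "Z"), seed = 1))
    mean(sapply(alleleCounts(pan, "cluster")$counts$X, expectedHet))
  })
  cfg0 <- simConfig("X",
    sampleSizes = c(X = N), demeSize = N, founderSize = N,
    generations = 1L, migrationScale = 0, mutationRate = 0,
    selfingRate = 0, founderDivergence = 0, missingRate = 0, seed = 1
  )
  h0 <- mean(replicate(20, {
    cfg0$seed <- sample.int(1e6, 1)
    pan <- simulatePanel(cfg0, generateVectorNetwork(c("X", "Z"), seed = 1))
    mean(sapply(alleleCounts(pan, "cluster")$counts$X, expectedHet))
  }))
  expected <- h0 * (1 - 1 / (2 * N))^(gens - 1)
  expect_equal(mean(h), expected, tolerance = 0.06)
})

test_that("realized migrant counts track the network weights", {
  set.seed(51)
  w <- generateVectorNetwork(LETTERS[1:4], 1000, seed = 52)
  cfg <- simConfig(LETTERS[1:4],
    sampleSizes = setNames(rep(10L, 4), LETTERS[1:4]),
    migrationScale = 0.1, generations = 30L, demeSize = 200L,
    missingRate = 0, seed = 53
  )
  det <- simulatePanel(cfg, w, details = TRUE)
  mig <- det$migrantCounts
  # expected inbound split per recipient is proportional to column weights
  for (j in 1:4) {
    expFrac <- w[-j, j] / sum(w[-j, j])
    obsFrac <- mig[-j, j] / sum(mig[-j, j])
    expect_gt(cor(expFrac, obsFrac), 0.9)
  }
})

test_that("the outlier deme carries the most private alleles", {
  top <- sapply(1:5, function(s) {
    set.seed(s)
    ss <- sample.int(2^30, 2)
    w <- generateVectorNetwork(studyDesign()$demes, seed = ss[1])
    pan <- suppressWarnings(simulatePanel(studyConfig(outlier = TRUE, seed = ss[2]), w))
    pa <- privateAlleles(alleleCounts(pan, by = "cluster"))
    pa$group[which.max(pa$proportion)] == "PS"
  })
  expect_gte(sum(top), 4)
})
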