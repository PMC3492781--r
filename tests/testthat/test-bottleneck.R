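# Heterozygosity-excess bottleneck machinery.

test_that("signed-rank p-values match closed cases and enumeration", {
  # all five loci above reference: one-tailed excess p = 1/2^5
  expect_equal(wilcoxonHetTest(rep(0.8, 5), rep(0.5, 5), "excess"), 1 / 32)
  # balanced symmetric differences: two-sided p = 1
  d <- c(0.1, -0.1, 0.2, -0.2)
  expect_equal(wilcoxonHetTest(d, rep(0, 4), "two.sided"), 1)
  # signed ranks (+1..+5, -6) against exhaustive 2^6 enumeration
  obs <- c(0.01, 0.02, 0.03, 0.04, 0.05, -0.06)
  for (tail in c("excess", "deficit", "two.sided")) {
    expect_equal(
      wilcoxonHetTest(obs, rep(0, 6), tail),
      oracleWilcoxon(obs, tail),
      tolerance = 1e-12
    )
  }
  # tie-free case agrees with stats::wilcox.test exact one-tailed
  set.seed(2)
  x <- round(rnorm(9), 3)
  expect_equal(
    wilcoxonHetTest(x, rep(0, 9), "excess"),
    stats::wilcox.test(x, alternative = "greater", exact = TRUE)$p.value,
    tolerance = 1e-12
  )
  expect_warning(pz <- wilcoxonHetTest(rep(0.4, 5), rep(0.4, 5)), "zero")
  expect_equal(pz, 1)
  # normal approximation branch is close to exact at the boundary size
  set.seed(3)
  y <- rnorm(21)
  approx <- wilcoxonHetTest(y, rep(0, 21), "excess")
  exact21 <- stats::wilcox.test(y, alternative = "greater", exact = TRUE)$p.value
  expect_equal(approx, exact21, tolerance = 0.01)
})

test_that("equilibrium simulator is deterministic and saturates correctly", {
  e1 <- equilibriumHet(30, 4, nSims = 200, nCal = 200, seed = 5)
  e2 <- equilibriumHet(30, 4, nSims = 200, nCal = 200, seed = 5)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$sd, e2$sd)
  expect_error(equilibriumHet(10, 1), "kObs")
  expect_error(equilibriumHet(10, 4, nSims = 50), "nSims")
  # k close to n forces high heterozygosity
  sat <- equilibriumHet(12, 11, nSims = 150, nCal = 200, seed = 6)
  expect_gt(sat$mean, 0.85)
})

test_that("pure-SMM simulated diversity tracks the closed form", {
  set.seed(7)
  q <- (-1 + sqrt(1 + 4 * 12)) / (2 * 12)
  for (theta in c(1, 2, 4)) {
    sims <- vecgen:::cpp_tpm_coalescent(60L, theta, 0, q, 3000L)
    expect_equal(mean(sims$H), 1 - 1 / sqrt(1 + 2 * theta), tolerance = 0.02)
  }
})

test_that("mode-shift detection follows the L-shape rule", {
  lshaped <- c(rep(0.02, 12), rep(0.15, 4), 0.55, 0.72)
  ms <- modeShift(lshaped)
  expect_false(ms$modeShift)
  expect_equal(sum(ms$histogram), length(lshaped))
  shifted <- modeShift(rep(0.5, 6)) # lowest class empty
  expect_true(shifted$modeShift)
})

test_that("standardized differences are centred near zero at equilibrium", {
  set.seed(8)
  q <- (-1 + sqrt(1 + 4 * 12)) / (2 * 12)
  sims <- vecgen:::cpp_tpm_coalescent(60L, 2, 0.1, q, 120L)
  keep <- which(sims$k >= 3 & sims$k <= 7)[1:40]
  cache <- new.env()
  dh <- sapply(keep, function(i) {
    key <- as.character(sims$k[i])
    if (!exists(key, cache)) {
      assign(key, equilibriumHet(60L, sims$k[i], nSims = 500, nCal = 300), cache)
    }
    eq <- get(key, cache)
    (sims$H[i] - eq$mean) / eq$sd
  })
  expect_lt(abs(mean(dh)), 0.35)
})

test_that("a recent collapse shows heterozygosity excess more often than equilibrium", {
  runPanel <- function(seed, bottleneck) {
    cfg <- simConfig("X",
      sampleSizes = c(X = 25L), demeSize = 400L,
      generations = 16L, migrationScale = 0, missingRate = 0,
      mutationRate = 2e-3, allelesPerLocus = 6L,
      bottleneckGeneration = if (bottleneck) 13L else NULL,
      bottleneckSize = if (bottleneck) 30L else NULL,
      seed = seed
    )
    pan <- simulatePanel(cfg, generateVectorNetwork(c("X", "Z"), seed = 1))
    bt <- try(
      suppressWarnings(
        bottleneckTest(pan, nSims = 300, seed = seed + 1)
      ),
      silent = TRUE
    )
    if (inherits(bt, "try-error")) NA else bt$X$p["excess"]
  }
  pEq <- sapply(1:10, runPanel, bottleneck = FALSE)
  pBn <- sapply(11:20, runPanel, bottleneck = TRUE)
  expect_lt(median(pBn, na.rm = TRUE), median(pEq, na.rm = TRUE))
})

test_that("bottleneckTest reports per-cluster tables with finite DH", {
  p <- twoDemePanel(seed = 91, nPerDeme = 25L)
  bt <- suppressWarnings(bottleneckTest(p, nSims = 200, seed = 92))
  expect_named(bt, c("X", "Y"))
  for (g in names(bt)) {
    expect_gte(nrow(bt[[g]]$perLocus), 4L)
    expect_true(all(is.finite(bt[[g]]$perLocus$DH)))
    expect_true(all(bt[[g]]$p > 0 & bt[[g]]$p <= 1))
    expect_equal(
      sum(bt[[g]]$histogram),
      sum(sapply(alleleCounts(p)$counts[[g]], length))
    )
  }
})
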