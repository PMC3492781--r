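# Descriptive and differentiation statistics.

test_that("allele counts tally gene copies and handle missing data", {
  p <- panelFromStrings(
    list(c("A/A", "A/B"), c("A/B", "-")),
    site = c("s1", "s1")
  )
  ft <- alleleCounts(p, by = "site")
  expect_equal(unname(ft$counts$s1$L1), c(3L, 1L)) # A:3, B:1
  expect_equal(sum(ft$counts$s1$L2), 2L) # missing individual excluded
  # additivity: per-cluster counts sum to the pooled counts
  p2 <- twoDemePanel(seed = 3)
  byClust <- alleleCounts(p2, by = "cluster")
  pooled <- alleleCounts(p2, by = "all")
  for (l in locNames(p2)) {
    merged <- tapply(
      unlist(lapply(byClust$counts, function(cl) cl[[l]])),
      unlist(lapply(byClust$counts, function(cl) names(cl[[l]]))),
      sum
    )
    pooledTab <- tapply(
      pooled$counts$all[[l]], names(pooled$counts$all[[l]]), sum
    )
    nm <- sort(names(pooledTab))
    expect_equal(merged[nm], pooledTab[nm])
  }
})

test_that("unbiased gene diversity matches pair-counting oracle", {
  # {A:3, B:1}: 3 of the 6 unordered gene-copy pairs differ
  expect_equal(expectedHet(c(A = 3, B = 1)), 3 / 6)
  expect_equal(expectedHet(c(A = 7)), 0) # monomorphic
  expect_true(is.na(expectedHet(c(A = 1)))) # n < 2 undefined
  # two alleles at 50/50: approaches 0.5 from above as n grows
  expect_equal(expectedHet(c(A = 5000, B = 5000)), 0.5, tolerance = 1e-3)
  # translation invariance of allele sizes
  expect_equal(
    expectedHet(c("10" = 4, "12" = 3, "15" = 1)),
    expectedHet(c("20" = 4, "22" = 3, "25" = 1))
  )
})

test_that("rarefied allelic richness matches subset enumeration", {
  counts <- c(A = 6, B = 2)
  # enumerate all C(8, g) subsets of the 8 gene copies
  copies <- rep(c(1, 2), counts)
  for (g in c(1, 2, 3, 5)) {
    subsets <- combn(8, g)
    enum <- mean(apply(subsets, 2, function(s) length(unique(copies[s]))))
    expect_equal(allelicRichness(counts, g), enum, tolerance = 1e-12)
  }
  expect_equal(allelicRichness(counts, 2), 10 / 7)
  expect_equal(allelicRichness(counts, 8), 2) # g = n: observed count
  expect_true(is.na(allelicRichness(counts, 9))) # g > n
  # nondecreasing in g, bounded by the observed allele count
  ar <- sapply(1:8, allelicRichness, counts = counts)
  expect_true(all(diff(ar) >= -1e-12))
  expect_true(all(ar <= 2 + 1e-12))
})

test_that("F_IS sign conventions and selfing equilibrium hold", {
  allHet <- panelFromStrings(
    replicate(6, c("A/B"), simplify = FALSE),
    site = rep("s", 6)
  )
  expect_lt(fisEstimate(allHet, by = "site")["s"], 0)
  noHet <- panelFromStrings(
    c(replicate(3, c("A/A"), simplify = FALSE), replicate(3, c("B/B"), simplify = FALSE)),
    site = rep("s", 6)
  )
  expect_equal(unname(fisEstimate(noHet, by = "site")["s"]), 1)
  # partial selfing at rate s: equilibrium F_IS = s/(2 - s) = 0.25 at s = 0.4
  cfg <- simConfig("X",
    sampleSizes = c(X = 250L), selfingRate = 0.4,
    migrationScale = 0, demeSize = 600L, generations = 25L,
    missingRate = 0, seed = 77
  )
  pan <- simulatePanel(cfg, generateVectorNetwork(c("X", "Z"), seed = 1)[, , drop = FALSE])
  expect_lt(abs(fisEstimate(pan, by = "cluster")["X"] - 0.25), 0.06)
  # s = 0: F_IS near zero
  cfg0 <- simConfig("X",
    sampleSizes = c(X = 250L), selfingRate = 0,
    migrationScale = 0, demeSize = 600L, generations = 25L,
    missingRate = 0, seed = 78
  )
  pan0 <- simulatePanel(cfg0, generateVectorNetwork(c("X", "Z"), seed = 1))
  expect_lt(abs(fisEstimate(pan0, by = "cluster")["X"]), 0.06)
})

test_that("pairwise theta matches the variance-component oracle", {
  # printed toy: cluster 1 = {A/A, A/A}, cluster 2 = {A/B, B/B}
  toy <- panelFromStrings(
    list("A/A", "A/A", "A/B", "B/B"),
    site = c("c1", "c1", "c2", "c2")
  )
  theta <- pairwiseFst(toy)["c1", "c2"]
  expect_equal(theta, oracleWC(toy), tolerance = 1e-12)
  expect_equal(theta, 2 / 3, tolerance = 1e-12)
  # complete differentiation
  fixed <- panelFromStrings(
    list(c("A/A", "C/C"), c("A/A", "C/C"), c("B/B", "D/D"), c("B/B", "D/D")),
    site = c("c1", "c1", "c2", "c2")
  )
  expect_equal(unname(pairwiseFst(fixed)["c1", "c2"]), 1)
  # null case: two samples from one deme
  cfg <- simConfig("X",
    sampleSizes = c(u = 40L, v = 40L),
    siteCluster = c(u = "X", v = "X"),
    migrationScale = 0, missingRate = 0, seed = 5
  )
  pan <- simulatePanel(cfg, generateVectorNetwork(c("X", "Z"), seed = 2))
  clusters(pan) <- sites(pan)
  expect_lt(abs(pairwiseFst(pan)["u", "v"]), 0.03)
  # matrix structure and allele-relabeling invariance
  p2 <- twoDemePanel(seed = 9)
  f <- pairwiseFst(p2)
  expect_true(isSymmetric(f))
  expect_equal(unname(diag(f)), rep(0, 2))
  relab <- GenotypePanel(900L - p2@alleleA, 900L - p2@alleleB,
    site = sites(p2), cluster = clusters(p2)
  )
  expect_equal(pairwiseFst(relab), f, tolerance = 1e-12)
})

test_that("negative theta is retained unless truncated", {
  set.seed(10)
  cfg <- simConfig("X",
    sampleSizes = c(u = 15L, v = 15L),
    siteCluster = c(u = "X", v = "X"),
    migrationScale = 0, missingRate = 0, seed = 11
  )
  pan <- simulatePanel(cfg, generateVectorNetwork(c("X", "Z"), seed = 3))
  clusters(pan) <- sites(pan)
  raw <- replicate(1, pairwiseFst(pan)["u", "v"])
  trunc <- pairwiseFst(pan, truncate = TRUE)["u", "v"]
  expect_gte(trunc, 0)
  if (raw < 0) expect_equal(trunc, 0)
})

test_that("private alleles are exclusive by definition", {
  p <- panelFromStrings(
    list(c("A/B", "C/C"), c("A/A", "C/D"), c("A/B", "C/C"), c("A/A", "C/C")),
    site = c("c1", "c1", "c2", "c2")
  )
  pa <- privateAlleles(alleleCounts(p, by = "cluster"))
  # allele B (L1) in both clusters? c1 has A,B; c2 has A,B -> shared;
  # D at L2 only in c1
  expect_equal(pa$n_private[pa$group == "c1"], 1L)
  expect_equal(pa$n_private[pa$group == "c2"], 0L)
  expect_equal(pa$proportion[pa$group == "c1"], 1 / 4)
  mono <- panelFromStrings(
    list("A/A", "A/A"),
    site = c("c1", "c2")
  )
  pm <- privateAlleles(alleleCounts(mono, by = "cluster"))
  expect_true(all(pm$proportion == 0))
})

test_that("statistics are invariant under individual reordering", {
  p <- twoDemePanel(seed = 21)
  ord <- sample(nInd(p))
  q <- p[ord, ]
  expect_equal(sort(fisEstimate(p)), sort(fisEstimate(q)))
  expect_equal(
    pairwiseFst(p)[c("X", "Y"), c("X", "Y")],
    pairwiseFst(q)[c("X", "Y"), c("X", "Y")]
  )
  dp <- diversitySummary(p, g = 20L)
  dq <- diversitySummary(q, g = 20L)
  expect_equal(dp[order(dp$group), -1], dq[order(dq$group), -1],
    ignore_attr = TRUE
  )
})
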