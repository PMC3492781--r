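# Rank-based Mantel machinery.

labeledMatrix <- function(x, labels) {
  matrix(x, length(labels), length(labels), dimnames = list(labels, labels))
}

test_that("rank transform uses mid-ranks and preserves order", {
  m <- labeledMatrix(0, letters[1:3])
  m[row(m) != col(m)] <- c(3, 1, 2, 6, 5, 4)
  r <- rankTransform(m)
  expect_equal(r[row(r) != col(r)], c(3, 1, 2, 6, 5, 4))
  # ties share mid-ranks
  t2 <- labeledMatrix(0, letters[1:4])
  off <- row(t2) != col(t2)
  t2[off] <- c(1, 1, rep(5, 10))
  rt <- rankTransform(t2)
  expect_equal(sort(unique(rt[off])), c(1.5, 7.5))
  # invariant under monotone transforms
  a <- labeledMatrix(0, letters[1:4])
  a[off] <- runif(12)
  expect_equal(rankTransform(a)[off], rankTransform(exp(3 * a))[off])
  flat <- labeledMatrix(1, letters[1:3])
  expect_warning(rankTransform(flat), "uninformative")
})

test_that("self-correlation gives R = 1 at the permutation floor", {
  set.seed(101)
  a <- labeledMatrix(0, letters[1:6])
  a[row(a) != col(a)] <- runif(30)
  res <- mantelRank(a, a, nPerm = 99, seed = 1)
  expect_equal(res@R, 1)
  expect_equal(res@P, 1 / 100)
})

test_that("exact mode equals full permutation enumeration", {
  set.seed(102)
  labels <- letters[1:4]
  a <- labeledMatrix(0, labels)
  b <- labeledMatrix(0, labels)
  a[row(a) != col(a)] <- runif(12)
  b[row(b) != col(b)] <- runif(12)
  res <- mantelRank(a, b, tail = "greater", exact = TRUE)
  perms <- oraclePerms(4)
  stats <- apply(perms, 1, function(p) {
    oracleMantelStat(a, b[p, p])
  })
  expect_equal(res@R, oracleMantelStat(a, b), tolerance = 1e-12)
  expect_equal(res@P, mean(stats >= res@R - 1e-12), tolerance = 1e-12)
  expect_equal(res@nPerm, factorial(4) - 1L)
})

test_that("R is symmetric in its arguments and seeded runs reproduce", {
  set.seed(103)
  labels <- letters[1:7]
  a <- labeledMatrix(0, labels)
  b <- labeledMatrix(0, labels)
  a[row(a) != col(a)] <- rnorm(42)
  b[row(b) != col(b)] <- rnorm(42)
  r1 <- mantelRank(a, b, nPerm = 199, seed = 7)
  r2 <- mantelRank(b, a, nPerm = 199, seed = 7)
  expect_equal(r1@R, r2@R, tolerance = 1e-12)
  expect_identical(
    mantelRank(a, b, nPerm = 199, seed = 8)@P,
    mantelRank(a, b, nPerm = 199, seed = 8)@P
  )
})

test_that("label exclusion equals testing pre-sliced matrices", {
  set.seed(104)
  labels <- letters[1:7]
  a <- labeledMatrix(0, labels)
  b <- labeledMatrix(0, labels)
  a[row(a) != col(a)] <- rnorm(42)
  b[row(b) != col(b)] <- rnorm(42)
  keep <- setdiff(labels, c("c", "f"))
  r1 <- mantelRank(a, b, nPerm = 199, seed = 9, exclude = c("c", "f"))
  r2 <- mantelRank(a[keep, keep], b[keep, keep], nPerm = 199, seed = 9)
  expect_equal(r1@R, r2@R)
  expect_identical(r1@P, r2@P)
})

test_that("misaligned and degenerate inputs are rejected", {
  a <- labeledMatrix(rnorm(16), letters[1:4])
  b <- labeledMatrix(rnorm(16), letters[2:5])
  expect_error(mantelRank(a, b), "label mismatch.*only in first")
  flat <- labeledMatrix(1, letters[1:4])
  diag(flat) <- 0
  suppressWarnings(expect_error(
    mantelRank(flat + diag(4) * 0, flat),
    "degenerate"
  ))
  small <- labeledMatrix(rnorm(9), letters[1:3])
  expect_error(mantelRank(small, small), "at least 4")
  # matrix row order must not matter once labels align
  set.seed(105)
  c1 <- labeledMatrix(0, letters[1:5])
  c2 <- labeledMatrix(0, letters[1:5])
  c1[row(c1) != col(c1)] <- rnorm(20)
  c2[row(c2) != col(c2)] <- rnorm(20)
  shuffled <- c2[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)]
  expect_equal(
    mantelRank(c1, c2, nPerm = 99, seed = 2)@R,
    mantelRank(c1, shuffled, nPerm = 99, seed = 2)@R
  )
})

test_that("symmetric-case R agrees with vegan's Spearman Mantel statistic", {
  skip_if_not_installed("vegan")
  set.seed(106)
  d1 <- as.matrix(dist(matrix(rnorm(14), 7)))
  d2 <- as.matrix(dist(matrix(rnorm(14), 7)))
  ours <- mantelRank(d1, d2, nPerm = 99, seed = 3)@R
  veg <- vegan::mantel(d1, d2, method = "spearman", permutations = 9)$statistic
  expect_equal(ours, unname(veg), tolerance = 1e-10)
})

test_that("correlation tables cover all pairs in the printed layout", {
  set.seed(107)
  labels <- letters[1:6]
  mats <- lapply(1:4, function(i) {
    m <- labeledMatrix(0, labels)
    m[row(m) != col(m)] <- rnorm(30)
    m
  })
  names(mats) <- c("FST", "Distance", "Migration", "Shipping")
  ct <- correlationTable(mats, nPerm = 99, seed = 4)
  expect_length(ct$results, 6L) # 4 choose 2
  expect_true(all(is.na(diag(ct$table))))
  expect_equal(ct$table["FST", "Distance"], ct$results[["FST~Distance"]]@R)
  expect_equal(ct$table["Distance", "FST"], ct$results[["FST~Distance"]]@P)
  two <- correlationTable(mats[1:2], nPerm = 99, seed = 5)
  expect_length(two$results, 1L)
  # exclusion produces both variants
  both <- correlationTable(mats, nPerm = 99, seed = 6, exclude = "a")
  expect_named(both, c("full", "excluded"))
  expect_equal(both$excluded$results[[1]]@nLabels, 5L)
})

test_that("permuting either matrix gives an equivalent null", {
  set.seed(108)
  labels <- letters[1:6]
  a <- labeledMatrix(0, labels)
  b <- labeledMatrix(0, labels)
  a[row(a) != col(a)] <- rnorm(30)
  b[row(b) != col(b)] <- rnorm(30)
  pAB <- replicate(30, mantelRank(a, b, nPerm = 99)@P)
  pBA <- replicate(30, mantelRank(b, a, nPerm = 99)@P)
  # same null: distributions of P overlap (medians within 0.25)
  expect_lt(abs(median(pAB) - median(pBA)), 0.25)
})
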