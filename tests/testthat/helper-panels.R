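# Shared fixture builders: tiny deterministic panels and independent
# oracle implementations used across test files.

# Panel from a list of per-individual genotype string vectors like
# c("A/A", "A/B"), one string per locus; "-" = missing.
panelFromStrings <- function(genos, site, cluster = site) {
  L <- length(genos[[1]])
  code <- function(x) {
    # letters -> integer allele sizes
    if (x == "-") c(NA_integer_, NA_integer_) else {
      match(strsplit(x, "/")[[1]], LETTERS) + 9L
    }
  }
  a <- matrix(NA_integer_, length(genos), L)
  b <- matrix(NA_integer_, length(genos), L)
  for (i in seq_along(genos)) {
    for (l in seq_len(L)) {
      al <- code(genos[[i]][l])
      a[i, l] <- al[1]
      b[i, l] <- al[2]
    }
  }
  colnames(a) <- paste0("L", seq_len(L))
  GenotypePanel(a, b, site = site, cluster = cluster)
}

# Two-deme panel with strong differentiation, for assignment/cluster tests.
twoDemePanel <- function(seed = 1, nPerDeme = 30L, divergence = 0.6,
                         m = 0) {
  cfg <- simConfig(c("X", "Y"),
    sampleSizes = c(X = nPerDeme, Y = nPerDeme),
    founderDivergence = divergence, migrationScale = m,
    generations = 15L, demeSize = 150L, missingRate = 0,
    seed = seed
  )
  w <- generateVectorNetwork(c("X", "Y"), seed = seed + 1000L)
  simulatePanel(cfg, w)
}

# Independent Weir & Cockerham (1984) variance components, written from the
# per-locus definitions; used as the oracle for theta and f.
oracleWC <- function(panel) {
  g <- clusters(panel)
  pops <- unique(g)
  r <- length(pops)
  A <- panel@alleleA
  B <- panel@alleleB
  tot <- c(a = 0, b = 0, cc = 0)
  for (l in seq_len(ncol(A))) {
    typed <- !is.na(A[, l])
    n_i <- sapply(pops, function(p) sum(typed & g == p))
    if (any(n_i == 0)) next
    alleles <- unique(c(A[typed, l], B[typed, l]))
    if (length(alleles) < 2) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- sapply(pops, function(p) {
        k <- typed & g == p
        (sum(A[k, l] == al) + sum(B[k, l] == al)) / (2 * sum(k))
      })
      h_i <- sapply(pops, function(p) {
        k <- typed & g == p
        mean((A[k, l] == al) != (B[k, l] == al))
      })
      pbar <- sum(n_i * p_i) / (r * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      tot <- tot + c(a, b, hbar / 2)
    }
  }
  unname(tot["a"] / sum(tot))
}

# Exhaustive signed-rank oracle: p over all 2^L sign patterns.
oracleWilcoxon <- function(d, tail) {
  d <- d[d != 0]
  L <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  ws <- sapply(0:(2^L - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:L] == 1L
    sum(r[signs])
  })
  switch(tail,
    excess = mean(ws >= wobs - 1e-9),
    deficit = mean(ws <= wobs + 1e-9),
    two.sided = min(1, 2 * min(mean(ws >= wobs - 1e-9), mean(ws <= wobs + 1e-9)))
  )
}

# All permutations of 1..n, independent of the package's internal helper.
oraclePerms <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(x) length(unique(x)) == n), , drop = FALSE]
}

# Spearman Mantel statistic computed directly from definitions.
oracleMantelStat <- function(a, b) {
  off <- row(a) != col(a)
  cor(rank(a[off]), rank(b[off]))
}
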