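## Descriptive and differentiation statistics for diploid microsatellite
## panels: allele counts/frequencies, unbiased gene diversity, rarefied
## allelic richness, Weir-Cockerham f (F_IS) and pairwise theta (F_ST),
## private alleles.

#' Allele counts per group and locus
#'
#' Counts gene copies (two per fully typed individual) for each allele at
#' each locus within each group. Missing genotypes are excluded locus-wise,
#' so an individual untyped at one locus still contributes two copies at the
#' others.
#'
#' @param panel a [GenotypePanel-class].
#' @param by grouping level: `"cluster"`, `"site"`, or `"all"` (one pooled
#'   group).
#' @return An object of class `AlleleFrequencyTable`: a list with elements
#'   `groups`, `loci`, and `counts` where `counts[[group]][[locus]]` is a
#'   named integer vector mapping allele size to gene-copy count.
#'   `as.data.frame()` gives the long form.
#' @examples
#' p <- GenotypePanel(
#'   matrix(c(10L, 10L), 2, 1, dimnames = list(NULL, "L1")),
#'   matrix(c(10L, 12L), 2, 1), site = c("A", "A")
#' )
#' alleleCounts(p)$counts$A$L1 # 10 -> 3, 12 -> 1
#' @export
alleleCounts <- function(panel, by = c("cluster", "site", "all")) {
  by <- match.arg(by)
  g <- switch(by,
    cluster = clusters(panel),
    site = sites(panel),
    all = rep("all", nInd(panel))
  )
  groups <- unique(g)
  loci <- locNames(panel)
  counts <- lapply(groups, function(grp) {
    keep <- g == grp
    if (!any(keep)) {
      message("empty group '", grp, "' in allele counting")
    }
    a <- panel@alleleA[keep, , drop = FALSE]
    b <- panel@alleleB[keep, , drop = FALSE]
    out <- lapply(seq_along(loci), function(l) {
      copies <- c(a[, l], b[, l])
      copies <- copies[!is.na(copies)]
      if (!length(copies)) {
        return(integer(0))
      }
      tab <- table(copies)
      setNames(as.integer(tab), names(tab))
    })
    names(out) <- loci
    out
  })
  names(counts) <- groups
  structure(list(groups = groups, loci = loci, counts = counts),
    class = "AlleleFrequencyTable"
  )
}

#' @export
as.data.frame.AlleleFrequencyTable <- function(x, ...) {
  rows <- list()
  for (grp in x$groups) {
    for (loc in x$loci) {
      cnt <- x$counts[[grp]][[loc]]
      if (!length(cnt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, locus = loc,
        allele = as.integer(names(cnt)),
        count = as.integer(cnt),
        freq = as.numeric(cnt) / sum(cnt)
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.AlleleFrequencyTable <- function(x, ...) {
  cat(
    "AlleleFrequencyTable:", length(x$groups), "group(s) x",
    length(x$loci), "loci\n"
  )
  invisible(x)
}

#' Unbiased expected heterozygosity at one locus
#'
#' Nei's unbiased gene diversity, `(n/(n-1)) * (1 - sum(p_j^2))` with `n`
#' gene copies: the probability that two gene copies drawn without
#' replacement differ.
#'
#' @param counts named integer vector of allele gene-copy counts at a locus.
#' @return Numeric in `[0, 1]`, or `NA` when fewer than 2 gene copies.
#' @examples
#' expectedHet(c(A = 3, B = 1)) # 0.5
#' @export
expectedHet <- function(counts) {
  n <- sum(counts)
  if (n < 2) {
    return(NA_real_)
  }
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' `A_R(g) = sum_j [1 - choose(n - n_j, g) / choose(n, g)]`.
#'
#' @param counts named integer vector of allele gene-copy counts at a locus.
#' @param g rarefaction depth in gene copies (`2 x` individuals).
#' @return Numeric; `NA` when `g` exceeds the available gene copies.
#' @examples
#' allelicRichness(c(A = 6, B = 2), g = 2) # 10/7
#' @export
allelicRichness <- function(counts, g) {
  n <- sum(counts)
  if (g > n) {
    return(NA_real_)
  }
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

## Weir & Cockerham per-locus, per-allele variance components for r groups.
## Returns matrix with columns a, b, c summed over alleles, or zero rows for
## uninformative loci. n_i are typed-individual counts per group.
wcComponents <- function(nA, nB, grp) {
  groups <- unique(grp)
  r <- length(groups)
  comps <- matrix(0, 0, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (l in seq_len(ncol(nA))) {
    typed <- !is.na(nA[, l])
    n_i <- vapply(groups, function(g) sum(typed & grp == g), 0L)
    use <- n_i > 0L
    if (sum(use) < r) next # every group must have data at this locus
    alleles <- sort(unique(c(nA[typed, l], nB[typed, l])))
    if (length(alleles) < 2L) next
    nbar <- mean(n_i)
    nc <- if (r > 1) (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else NA
    for (al in alleles) {
      p_i <- vapply(groups, function(g) {
        k <- typed & grp == g
        (sum(nA[k, l] == al) + sum(nB[k, l] == al)) / (2 * sum(k))
      }, 0)
      h_i <- vapply(groups, function(g) {
        k <- typed & grp == g
        sum((nA[k, l] == al) != (nB[k, l] == al)) / sum(k)
      }, 0)
      pbar <- sum(n_i * p_i) / (r * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      if (r > 1) {
        s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
        a <- (nbar / nc) *
          (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
      } else {
        a <- 0
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
      }
      comps <- rbind(comps, c(a, b, hbar / 2))
    }
  }
  comps
}

#' Weir-Cockerham fixation index F_IS per group
#'
#' Within-population f of Weir & Cockerham (1984), combined over loci and
#' alleles by the ratio of summed variance components:
#' `f = 1 - sum(c) / sum(b + c)`. Positive under heterozygote deficit.
#'
#' @param panel a [GenotypePanel-class].
#' @param by grouping level, `"cluster"` or `"site"`.
#' @return Named numeric vector of per-group f; `NA` where all loci are
#'   monomorphic.
#' @export
fisEstimate <- function(panel, by = c("cluster", "site")) {
  by <- match.arg(by)
  g <- if (by == "cluster") clusters(panel) else sites(panel)
  out <- vapply(unique(g), function(grp) {
    keep <- g == grp
    if (sum(keep) < 2) {
      return(NA_real_)
    }
    comps <- wcComponents(
      panel@alleleA[keep, , drop = FALSE],
      panel@alleleB[keep, , drop = FALSE],
      rep("one", sum(keep))
    )
    denom <- sum(comps[, "b"] + comps[, "c"])
    if (nrow(comps) == 0L || denom == 0) {
      return(NA_real_)
    }
    1 - sum(comps[, "c"]) / denom
  }, 0)
  setNames(out, unique(g))
}

#' Pairwise F_ST (Weir-Cockerham theta) between clusters
#'
#' Multi-locus, multi-allele theta by ratio of summed variance components for
#' every pair of groups. Negative estimates are retained by default (they are
#' informative in matrix correlation tests); set `truncate = TRUE` to clamp
#' at zero.
#'
#' @param panel a [GenotypePanel-class].
#' @param by grouping level, `"cluster"` or `"site"`.
#' @param truncate clamp negative estimates to 0.
#' @return Symmetric numeric matrix with zero diagonal, labeled by group.
#' @export
pairwiseFst <- function(panel, by = c("cluster", "site"), truncate = FALSE) {
  by <- match.arg(by)
  g <- if (by == "cluster") clusters(panel) else sites(panel)
  groups <- unique(g)
  if (length(groups) < 2) stop("need at least 2 groups for pairwise F_ST")
  for (grp in groups) {
    keep <- g == grp
    typedAny <- colSums(!is.na(panel@alleleA[keep, , drop = FALSE]))
    if (all(typedAny < 2)) {
      stop("cluster '", grp, "' has < 2 typed individuals at every locus")
    }
  }
  m <- matrix(0, length(groups), length(groups),
    dimnames = list(groups, groups)
  )
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in seq((i + 1), length(groups))) {
      keep <- g %in% groups[c(i, j)]
      comps <- wcComponents(
        panel@alleleA[keep, , drop = FALSE],
        panel@alleleB[keep, , drop = FALSE],
        g[keep]
      )
      denom <- sum(comps)
      theta <- if (nrow(comps) == 0L || denom == 0) NA_real_ else {
        sum(comps[, "a"]) / denom
      }
      if (truncate && !is.na(theta)) theta <- max(theta, 0)
      m[i, j] <- m[j, i] <- theta
    }
  }
  m
}

#' Private alleles per cluster
#'
#' An allele (locus/size combination) is private to a cluster when it is
#' observed in that cluster only. The reported proportion is the number of
#' private alleles divided by the total number of distinct alleles in the
#' dataset.
#'
#' @param freqTable an `AlleleFrequencyTable` from [alleleCounts()] computed
#'   at the cluster level.
#' @return A data.frame with columns `group`, `n_private`, `proportion`;
#'   attribute `"alleles"` holds a data.frame of each private allele with its
#'   within-cluster frequency.
#' @export
privateAlleles <- function(freqTable) {
  if (length(freqTable$groups) < 2) {
    stop("private alleles need at least 2 clusters")
  }
  long <- as.data.frame(freqTable)
  long$key <- paste(long$locus, long$allele, sep = ":")
  totalDistinct <- length(unique(long$key))
  occ <- tapply(long$group, long$key, function(g) length(unique(g)))
  privKeys <- names(occ)[occ == 1L]
  priv <- long[long$key %in% privKeys, , drop = FALSE]
  nPriv <- table(factor(priv$group, levels = freqTable$groups))
  out <- data.frame(
    group = freqTable$groups,
    n_private = as.integer(nPriv),
    proportion = as.integer(nPriv) / totalDistinct
  )
  attr(out, "alleles") <- priv[, c("group", "locus", "allele", "freq")]
  out
}

#' Per-group diversity summary
#'
#' One row per group: sample size `n`, mean observed alleles per locus
#' `N_A`, rarefied allelic richness `A_R` (mean over loci with at least `g`
#' gene copies), mean unbiased expected heterozygosity `H_E`, Weir-Cockerham
#' `F_IS`, and the private-allele proportion (cluster level only).
#'
#' @param panel a [GenotypePanel-class].
#' @param by grouping level, `"cluster"` or `"site"`.
#' @param g rarefaction depth in gene copies; the conventional depth for a
#'   minimum sample of 18 individuals is `g = 36`.
#' @return data.frame, one row per group.
#' @export
diversitySummary <- function(panel, by = c("cluster", "site"), g = 36L) {
  by <- match.arg(by)
  lab <- if (by == "cluster") clusters(panel) else sites(panel)
  ft <- alleleCounts(panel, by = by)
  priv <- if (length(ft$groups) >= 2) privateAlleles(ft) else NULL
  rows <- lapply(ft$groups, function(grp) {
    cl <- ft$counts[[grp]]
    nA <- mean(vapply(cl, length, 0L))
    he <- mean(vapply(cl, expectedHet, 0), na.rm = TRUE)
    ar <- vapply(cl, allelicRichness, 0, g = g)
    if (anyNA(ar)) {
      warning(
        "group '", grp, "': ", sum(is.na(ar)),
        " locus/loci with < ", g, " gene copies excluded from A_R"
      )
    }
    data.frame(
      group = grp, n = sum(lab == grp), N_A = nA,
      A_R = mean(ar, na.rm = TRUE), H_E = he
    )
  })
  out <- do.call(rbind, rows)
  out$F_IS <- unname(fisEstimate(panel, by = by)[out$group])
  out$private <- if (is.null(priv)) NA_real_ else {
    priv$proportion[match(out$group, priv$group)]
  }
  out
}
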