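## Rannala-Mountain Bayesian genotype assignment and the directional
## migration matrix built from modal assignments.

#' Rannala-Mountain log-likelihood of a multilocus genotype in one cluster
#'
#' Posterior-predictive probability of the genotype given the cluster's
#' allele counts under a `Dirichlet(1/k)` prior per locus, where `k` is the
#' dataset-wide number of distinct alleles at that locus. Per locus with
#' cluster gene-copy count `n` and allele counts `n_j`:
#' heterozygote (j1, j2): `2 (n_j1 + 1/k)(n_j2 + 1/k) / ((n+1)(n+2))`;
#' homozygote (j, j): `(n_j + 1/k)(n_j + 1 + 1/k) / ((n+1)(n+2))`.
#' Missing loci are skipped; an empty cluster at a locus yields the
#' prior-only term. The result is always finite: unseen alleles get prior
#' mass, never probability zero.
#'
#' @param genoA,genoB integer vectors of the two gene copies per locus
#'   (`NA` = missing).
#' @param clusterCounts list per locus of named gene-copy count vectors for
#'   the candidate cluster.
#' @param kPerLocus integer vector, dataset-wide distinct allele count per
#'   locus.
#' @return Log-likelihood (0 when every locus is missing).
#' @export
rmGenotypeLoglik <- function(genoA, genoB, clusterCounts, kPerLocus) {
  ll <- 0
  for (l in seq_along(genoA)) {
    x <- genoA[l]
    if (is.na(x)) next
    y <- genoB[l]
    cnt <- clusterCounts[[l]]
    n <- sum(cnt)
    invk <- 1 / kPerLocus[l]
    nx <- if (length(cnt)) sum(cnt[names(cnt) == as.character(x)]) else 0
    if (x == y) {
      term <- (nx + invk) * (nx + 1 + invk) / ((n + 1) * (n + 2))
    } else {
      ny <- if (length(cnt)) sum(cnt[names(cnt) == as.character(y)]) else 0
      term <- 2 * (nx + invk) * (ny + invk) / ((n + 1) * (n + 2))
    }
    ll <- ll + log(term)
  }
  ll
}

#' Assign every individual to its most likely source cluster
#'
#' Computes the Rannala-Mountain log-likelihood of each individual's
#' genotype in every cluster and records the modal (highest-likelihood)
#' cluster. With `leaveOneOut` (the default) the focal individual's own gene
#' copies are removed from its home cluster's counts before evaluation,
#' removing self-inclusion bias in small samples. Ties are broken by cluster
#' label order and flagged.
#'
#' @param panel a [GenotypePanel-class].
#' @param by grouping level, `"cluster"` or `"site"`.
#' @param leaveOneOut logical.
#' @return A data.frame of class `AssignmentResult` with columns
#'   `individual`, `home`, `modal`, `tie`; attribute `"loglik"` holds the
#'   full individuals x clusters log-likelihood matrix.
#' @export
assignIndividuals <- function(panel, by = c("cluster", "site"),
                              leaveOneOut = TRUE) {
  by <- match.arg(by)
  home <- if (by == "cluster") clusters(panel) else sites(panel)
  groups <- unique(home)
  if (any(!groups %in% home)) stop("empty cluster")
  L <- nLoc(panel)
  ft <- alleleCounts(panel, by = by)
  kPerLocus <- vapply(seq_len(L), function(l) {
    sizes <- unique(c(panel@alleleA[, l], panel@alleleB[, l]))
    max(sum(!is.na(sizes)), 1L)
  }, 0L)
  n <- nInd(panel)
  ll <- matrix(0, n, length(groups), dimnames = list(indNames(panel), groups))
  for (g in seq_along(groups)) {
    baseCounts <- ft$counts[[groups[g]]]
    for (i in seq_len(n)) {
      cc <- baseCounts
      if (leaveOneOut && home[i] == groups[g]) {
        for (l in seq_len(L)) {
          x <- panel@alleleA[i, l]
          if (is.na(x)) next
          y <- panel@alleleB[i, l]
          cl <- cc[[l]]
          cl[as.character(x)] <- cl[as.character(x)] - 1L
          cl[as.character(y)] <- cl[as.character(y)] - 1L
          cc[[l]] <- cl
        }
      }
      ll[i, g] <- rmGenotypeLoglik(
        panel@alleleA[i, ], panel@alleleB[i, ], cc, kPerLocus
      )
    }
  }
  modalIdx <- integer(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    best <- which(ll[i, ] >= max(ll[i, ]) - 1e-12)
    modalIdx[i] <- best[1L]
    tie[i] <- length(best) > 1L
  }
  if (any(tie)) {
    warning(sum(tie), " tied assignment(s) broken by cluster label order")
  }
  out <- data.frame(
    individual = indNames(panel), home = home,
    modal = groups[modalIdx], tie = tie
  )
  attr(out, "loglik") <- ll
  class(out) <- c("AssignmentResult", "data.frame")
  out
}

#' Directional migration matrix from modal assignments
#'
#' Cell `(source, recipient)` is the proportion of individuals sampled in
#' the recipient cluster whose modal assignment is the source cluster (rows
#' = source, columns = recipient); each column sums to 1 over sources
#' including self-assignment. With `excludeSelf = TRUE` the diagonal is
#' dropped and columns renormalised over off-diagonal sources (columns with
#' no migrants become 0).
#'
#' @param assignments an `AssignmentResult` from [assignIndividuals()].
#' @param excludeSelf logical.
#' @return Labeled square numeric matrix.
#' @export
migrationMatrix <- function(assignments, excludeSelf = FALSE) {
  groups <- unique(assignments$home)
  m <- matrix(0, length(groups), length(groups),
    dimnames = list(source = groups, recipient = groups)
  )
  for (g in groups) {
    rec <- assignments$modal[assignments$home == g]
    if (!length(rec)) stop("empty recipient cluster '", g, "'")
    tab <- table(factor(rec, levels = groups))
    m[, g] <- as.numeric(tab) / length(rec)
  }
  if (excludeSelf) {
    diag(m) <- 0
    cs <- colSums(m)
    nz <- cs > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  m
}
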