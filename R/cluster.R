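## Bayesian clustering: no-admixture Gibbs sampler over K clusters with
## uncorrelated Dirichlet(1) allele-frequency priors, replicate runs, and
## Evanno delta-K model choice.

## Encode panel genotypes as 0-based allele indices over the dataset-wide
## allele set at each locus (-1 = missing).
encodeAlleles <- function(panel) {
  L <- nLoc(panel)
  a1 <- matrix(-1L, nInd(panel), L)
  a2 <- matrix(-1L, nInd(panel), L)
  nAlleles <- integer(L)
  alleleSets <- vector("list", L)
  for (l in seq_len(L)) {
    sizes <- sort(unique(c(panel@alleleA[, l], panel@alleleB[, l])))
    sizes <- sizes[!is.na(sizes)]
    alleleSets[[l]] <- sizes
    nAlleles[l] <- max(length(sizes), 1L)
    idx1 <- match(panel@alleleA[, l], sizes) - 1L
    idx2 <- match(panel@alleleB[, l], sizes) - 1L
    a1[, l] <- ifelse(is.na(idx1), -1L, idx1)
    a2[, l] <- ifelse(is.na(idx2), -1L, idx2)
  }
  list(a1 = a1, a2 = a2, nAlleles = nAlleles, alleleSets = alleleSets)
}

#' Gibbs-sampler clustering of a genotype panel
#'
#' Fits the no-admixture model: each individual belongs wholly to one of K
#' clusters; cluster allele frequencies carry independent Dirichlet(1)
#' priors. The sampler alternates frequency draws from
#' `Dirichlet(1 + counts)` and label draws from each individual's full
#' conditional under Hardy-Weinberg within clusters. Membership fractions
#' are the posterior label frequencies after burn-in, and the model-choice
#' quantity is `L = mean(lnL) - var(lnL)/2` over the post-burn-in
#' log-likelihood trace.
#'
#' @param panel a [GenotypePanel-class].
#' @param K number of clusters (>= 1, at most the number of individuals).
#' @param burnIn,iters burn-in and retained sweeps.
#' @param seed integer RNG seed for the run.
#' @return A [ClusterModel-class].
#' @export
gibbsCluster <- function(panel, K, burnIn = 1000L, iters = 10000L,
                         seed = 1L) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > nInd(panel)) stop("K exceeds the number of individuals")
  if (iters < 1L) stop("iters must be > 0")
  enc <- encodeAlleles(panel)
  set.seed(seed)
  fit <- cpp_gibbs_cluster(enc$a1, enc$a2, enc$nAlleles, K,
    as.integer(burnIn), as.integer(iters))
  mem <- fit$zcount / iters
  rownames(mem) <- indNames(panel)
  colnames(mem) <- paste0("k", seq_len(K))
  post <- fit$trace[(burnIn + 1):(burnIn + iters)]
  new("ClusterModel",
    K = K, memberships = mem, loglikTrace = as.numeric(fit$trace),
    L = mean(post) - var(post) / 2,
    burnIn = as.integer(burnIn), iters = as.integer(iters),
    seed = as.integer(seed)
  )
}

#' Replicate runs over a ladder of K
#'
#' @param panel a [GenotypePanel-class].
#' @param Ks integer vector of K values (consecutive for Evanno use).
#' @param nReps replicate runs per K.
#' @param burnIn,iters per-run sweep counts.
#' @param seed base seed; run seeds are derived deterministically.
#' @return Named list (by K) of lists of [ClusterModel-class] objects.
#' @export
clusterScan <- function(panel, Ks = 1:8, nReps = 5L, burnIn = 1000L,
                        iters = 10000L, seed = 1L) {
  set.seed(seed)
  runSeeds <- matrix(
    sample.int(.Machine$integer.max, length(Ks) * nReps),
    nrow = length(Ks)
  )
  out <- lapply(seq_along(Ks), function(i) {
    lapply(seq_len(nReps), function(r) {
      gibbsCluster(panel, Ks[i], burnIn, iters, seed = runSeeds[i, r])
    })
  })
  names(out) <- as.character(Ks)
  out
}

#' Evanno delta-K model choice
#'
#' For each K with replicate runs, computes the mean and SD of
#' `L = ln P(X|K)` estimates, and for interior K the statistic
#' `deltaK = |meanL(K+1) - 2 meanL(K) + meanL(K-1)| / sdL(K)`. The selected
#' K maximises deltaK over interior values where it is defined.
#'
#' @param runs named list by K of lists of [ClusterModel-class] objects (or
#'   of bare numeric L values), as from [clusterScan()].
#' @return A data.frame of class `EvannoTable` with columns `K`, `meanL`,
#'   `sdL`, `deltaK`, and attribute `selectedK`.
#' @export
evannoSelect <- function(runs) {
  Ks <- as.integer(names(runs))
  if (length(Ks) < 3L || any(diff(sort(Ks)) != 1L)) {
    stop("need >= 3 consecutive K values")
  }
  o <- order(Ks)
  Ks <- Ks[o]
  runs <- runs[o]
  Ls <- lapply(runs, function(r) {
    vapply(r, function(m) if (is(m, "ClusterModel")) m@L else as.numeric(m), 0)
  })
  if (any(lengths(Ls) < 2L)) stop("need >= 2 replicate runs per K")
  meanL <- vapply(Ls, mean, 0)
  sdL <- vapply(Ls, sd, 0)
  deltaK <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-c(1L, length(Ks))]) {
    if (sdL[i] > 0) {
      deltaK[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1]) / sdL[i]
    } else {
      warning("sd(L) = 0 at K = ", Ks[i], "; deltaK undefined there")
    }
  }
  tab <- data.frame(K = Ks, meanL = meanL, sdL = sdL, deltaK = deltaK)
  rownames(tab) <- NULL
  sel <- if (all(is.na(deltaK)) || max(deltaK, na.rm = TRUE) == 0) {
    warning("deltaK uninformative; no K selected")
    NA_integer_
  } else {
    Ks[which.max(deltaK)]
  }
  attr(tab, "selectedK") <- sel
  class(tab) <- c("EvannoTable", "data.frame")
  tab
}

#' @export
print.EvannoTable <- function(x, ...) {
  cat("Evanno table (selected K =", attr(x, "selectedK"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Align cluster labels across replicate runs
#'
#' Repairs label switching: clusters of each run are greedily matched to the
#' first run's clusters, maximising the summed membership agreement, and the
#' membership columns are permuted accordingly. Deterministic given input
#' order.
#'
#' @param models list of [ClusterModel-class] objects with equal K.
#' @return List of relabeled models (a single model is returned unchanged).
#' @export
alignLabels <- function(models) {
  if (length(models) < 1L) stop("no models given")
  K <- unique(vapply(models, function(m) m@K, 0L))
  if (length(K) > 1L) stop("models have unequal K")
  if (length(models) == 1L) {
    return(models)
  }
  ref <- memberships(models[[1]])
  out <- models
  for (m in seq_along(models)[-1L]) {
    mem <- memberships(models[[m]])
    agree <- crossprod(ref, mem) # K x K summed products
    perm <- integer(K)
    usedR <- usedC <- rep(FALSE, K)
    for (step in seq_len(K)) {
      masked <- agree
      masked[usedR, ] <- -Inf
      masked[, usedC] <- -Inf
      best <- which(masked == max(masked), arr.ind = TRUE)[1L, ]
      perm[best["row"]] <- best["col"]
      usedR[best["row"]] <- TRUE
      usedC[best["col"]] <- TRUE
    }
    mod <- models[[m]]
    mod@memberships <- mem[, perm, drop = FALSE]
    colnames(mod@memberships) <- colnames(ref)
    out[[m]] <- mod
  }
  out
}

#' Modal cluster assignment of a fitted model
#'
#' @param model a [ClusterModel-class].
#' @return Integer vector of per-individual modal cluster indices.
#' @export
modalCluster <- function(model) {
  apply(memberships(model), 1L, which.max)
}

#' Membership agreement between two runs
#'
#' Mean over individuals of the overlap `sum_k min(m1[i,k], m2[i,k])`;
#' equals 1 for identical membership matrices.
#'
#' @param m1,m2 [ClusterModel-class] objects (after [alignLabels()]).
#' @return Numeric in `[0, 1]`.
#' @export
clusterAgreement <- function(m1, m2) {
  mean(rowSums(pmin(memberships(m1), memberships(m2))))
}
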