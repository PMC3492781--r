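#' @include AllGenerics.R
#' @import methods
#' @importFrom stats cor rbinom rgamma rgeom rnorm runif sd setNames var pnorm
#' @importFrom utils combn head read.table write.table
#' @importFrom tools md5sum
#' @useDynLib vecgen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

MISSING_ALLELE <- NA_integer_

#' GenotypePanel: diploid multi-locus microsatellite genotypes
#'
#' Container for a diploid codominant genotype table with per-individual site
#' and cluster labels. Allele values are positive integers on the
#' repeat-number scale; missing genotypes are `NA` (both gene copies at a
#' locus are missing together, as in standard GENEPOP coding).
#'
#' The two gene copies at a locus are stored in two parallel integer matrices
#' (`alleleA`, `alleleB`), with `alleleA <= alleleB` cell-wise so that the
#' unordered pair has a canonical representation.
#'
#' @slot alleleA integer matrix, individuals x loci; first (smaller) allele.
#' @slot alleleB integer matrix, individuals x loci; second allele.
#' @slot site character vector, per-individual site label.
#' @slot cluster character vector, per-individual cluster label.
#'
#' @seealso [GenotypePanel()] for construction, [readGenepop()] for file
#'   input, [simulatePanel()] for simulation.
#' @name GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    site = "character",
    cluster = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  a <- object@alleleA
  b <- object@alleleB
  msg <- character(0)
  if (!is.integer(a) || !is.integer(b)) {
    msg <- c(msg, "allele matrices must be integer")
  }
  if (!identical(dim(a), dim(b))) {
    msg <- c(msg, "alleleA and alleleB dimensions differ")
  }
  if (length(object@site) != nrow(a)) {
    msg <- c(msg, "site labels must match the number of individuals")
  }
  if (length(object@cluster) != nrow(a)) {
    msg <- c(msg, "cluster labels must match the number of individuals")
  }
  if (is.null(colnames(a))) {
    msg <- c(msg, "loci must be named (colnames of allele matrices)")
  }
  if (!identical(is.na(a), is.na(b))) {
    msg <- c(msg, "missing-data pattern must agree between the two gene copies")
  }
  ok <- !is.na(a)
  if (any(a[ok] < 1L) || any(b[!is.na(b)] < 1L)) {
    msg <- c(msg, "allele sizes must be positive integers")
  }
  if (any(a[ok] > b[ok])) {
    msg <- c(msg, "alleleA must be <= alleleB cell-wise (canonical pair order)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param alleleA,alleleB integer matrices (individuals x loci) holding the
#'   two gene copies of each genotype; order within the pair is irrelevant
#'   (pairs are canonicalised). `NA` marks missing genotypes and must occur
#'   in both matrices together.
#' @param site character vector of per-individual site labels.
#' @param cluster optional character vector of per-individual cluster labels;
#'   defaults to the site labels.
#' @return A [GenotypePanel-class] object.
#' @examples
#' a <- matrix(c(10L, 10L, 12L, 10L), 2, 2, dimnames = list(NULL, c("L1", "L2")))
#' b <- matrix(c(10L, 12L, 12L, 14L), 2, 2, dimnames = list(NULL, c("L1", "L2")))
#' GenotypePanel(a, b, site = c("S1", "S1"))
#' @export
GenotypePanel <- function(alleleA, alleleB, site, cluster = site) {
  alleleA <- as.matrix(alleleA)
  alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  if (is.null(colnames(alleleA))) {
    colnames(alleleA) <- paste0("L", seq_len(ncol(alleleA)))
  }
  colnames(alleleB) <- colnames(alleleA)
  if (is.null(rownames(alleleA))) {
    rownames(alleleA) <- paste0("ind", seq_len(nrow(alleleA)))
  }
  rownames(alleleB) <- rownames(alleleA)
  swap <- !is.na(alleleA) & !is.na(alleleB) & alleleA > alleleB
  if (any(swap)) {
    tmp <- alleleA[swap]
    alleleA[swap] <- alleleB[swap]
    alleleB[swap] <- tmp
  }
  new("GenotypePanel",
    alleleA = alleleA, alleleB = alleleB,
    site = as.character(site), cluster = as.character(cluster)
  )
}

#' @rdname nInd
#' @aliases nInd,GenotypePanel-method
setMethod("nInd", "GenotypePanel", function(x) nrow(x@alleleA))

#' @rdname nLoc
#' @aliases nLoc,GenotypePanel-method
setMethod("nLoc", "GenotypePanel", function(x) ncol(x@alleleA))

#' @rdname locNames
#' @aliases locNames,GenotypePanel-method
setMethod("locNames", "GenotypePanel", function(x) colnames(x@alleleA))

#' @rdname indNames
#' @aliases indNames,GenotypePanel-method
setMethod("indNames", "GenotypePanel", function(x) rownames(x@alleleA))

#' @rdname sites
#' @aliases sites,GenotypePanel-method
setMethod("sites", "GenotypePanel", function(x) x@site)

#' @rdname clusters
#' @aliases clusters,GenotypePanel-method
setMethod("clusters", "GenotypePanel", function(x) x@cluster)

#' @rdname clusters-set
#' @name clusters-set
#' @aliases clusters<-,GenotypePanel-method
#' @param x a [GenotypePanel-class].
#' @param value per-individual labels, or a named site -> cluster map.
#' @export
setReplaceMethod("clusters", "GenotypePanel", function(x, value) {
  value <- as.character(if (!is.null(names(value))) {
    mapped <- value[x@site]
    if (anyNA(mapped)) {
      stop(
        "cluster map does not cover site(s): ",
        paste(setdiff(unique(x@site), names(value)), collapse = ", ")
      )
    }
    mapped
  } else {
    value
  })
  x@cluster <- unname(value)
  validObject(x)
  x
})

#' @rdname genotypes
#' @aliases genotypes,GenotypePanel-method
setMethod("genotypes", "GenotypePanel", function(x) {
  arr <- array(NA_integer_, c(nInd(x), nLoc(x), 2L),
    dimnames = list(indNames(x), locNames(x), c("a1", "a2"))
  )
  arr[, , 1L] <- x@alleleA
  arr[, , 2L] <- x@alleleB
  arr
})

#' Subset a GenotypePanel
#'
#' `x[i, j]` keeps individuals `i` and loci `j` (any standard index type).
#'
#' @param x a [GenotypePanel-class].
#' @param i individual index.
#' @param j locus index.
#' @param ... ignored.
#' @param drop ignored (always `FALSE` semantics).
#' @return A [GenotypePanel-class].
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoc(x))
  if (is.character(i)) i <- match(i, indNames(x))
  new("GenotypePanel",
    alleleA = x@alleleA[i, j, drop = FALSE],
    alleleB = x@alleleB[i, j, drop = FALSE],
    site = x@site[i], cluster = x@cluster[i]
  )
})

setMethod("show", "GenotypePanel", function(object) {
  cat(
    "GenotypePanel with", nInd(object), "individuals x", nLoc(object),
    "loci\n"
  )
  us <- unique(object@site)
  cat("  sites:    ", length(us), " (", paste(head(us, 6L), collapse = ", "),
    if (length(us) > 6L) ", ..." else "", ")\n",
    sep = ""
  )
  cat("  clusters: ", length(unique(object@cluster)), "\n", sep = "")
  cat(sprintf("  missing:  %.1f%% of genotypes\n", 100 * mean(is.na(object@alleleA))))
})

#' ClusterModel: posterior summary of one Gibbs clustering run
#'
#' @slot K integer, number of clusters fitted.
#' @slot memberships numeric matrix individuals x K of posterior label
#'   frequencies (rows sum to 1).
#' @slot loglikTrace numeric vector of post-thinning data log-likelihood values
#'   (burn-in included; see `burnIn` for the recorded split).
#' @slot L numeric, model-choice estimate of ln P(X | K):
#'   `mean(lnL) - var(lnL)/2` over the post-burn-in trace.
#' @slot burnIn,iters integers, sweep counts.
#' @slot seed integer seed used for the run.
#' @name ClusterModel-class
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    K = "integer",
    memberships = "matrix",
    loglikTrace = "numeric",
    L = "numeric",
    burnIn = "integer",
    iters = "integer",
    seed = "integer"
  )
)

setValidity("ClusterModel", function(object) {
  m <- object@memberships
  msg <- character(0)
  if (ncol(m) != object@K) msg <- c(msg, "memberships must have K columns")
  if (any(m < -1e-9)) msg <- c(msg, "membership fractions must be >= 0")
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    msg <- c(msg, "membership fractions must sum to 1 per individual")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname memberships
#' @aliases memberships,ClusterModel-method
setMethod("memberships", "ClusterModel", function(x) x@memberships)

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: K =", object@K, "|", nrow(object@memberships),
    "individuals\n")
  cat(sprintf(
    "  ln P(X|K) estimate L = %.2f (burn-in %d, %d sweeps, seed %d)\n",
    object@L, object@burnIn, object@iters, object@seed
  ))
})

#' MantelResult: rank-based Mantel correlation between two labeled matrices
#'
#' @slot pair character(2), names of the matrices compared.
#' @slot R numeric, Spearman correlation of the paired off-diagonal cells
#'   (Pearson on mid-ranks).
#' @slot P numeric, permutation p-value.
#' @slot nPerm integer, permutations used.
#' @slot tail character, one of "greater", "less", "two.sided".
#' @slot excluded character, labels dropped before testing.
#' @slot nLabels integer, labels retained.
#' @name MantelResult-class
#' @exportClass MantelResult
setClass("MantelResult",
  representation(
    pair = "character",
    R = "numeric",
    P = "numeric",
    nPerm = "integer",
    tail = "character",
    excluded = "character",
    nLabels = "integer"
  )
)

setValidity("MantelResult", function(object) {
  msg <- character(0)
  if (!is.na(object@R) && abs(object@R) > 1 + 1e-9) {
    msg <- c(msg, "R must lie in [-1, 1]")
  }
  if (object@P <= 0 || object@P > 1) msg <- c(msg, "P must lie in (0, 1]")
  if (object@P < 1 / (object@nPerm + 1) - 1e-12) {
    msg <- c(msg, "P cannot be smaller than 1/(nPerm + 1)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf(
    "Mantel (ranked, %s): %s vs %s\n  R = %.4f, P = %.4g (%d permutations%s)\n",
    object@tail, object@pair[1], object@pair[2], object@R, object@P,
    object@nPerm,
    if (length(object@excluded)) {
      paste0("; excluded: ", paste(object@excluded, collapse = ", "))
    } else {
      ""
    }
  ))
})
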