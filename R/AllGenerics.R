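#' Number of individuals in a panel
#'
#' @param x a [GenotypePanel-class] object.
#' @return Integer count.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' Number of loci in a panel
#'
#' @param x a [GenotypePanel-class] object.
#' @return Integer count.
#' @export
setGeneric("nLoc", function(x) standardGeneric("nLoc"))

#' Locus names
#'
#' @param x a [GenotypePanel-class] object.
#' @return Character vector of locus names.
#' @export
setGeneric("locNames", function(x) standardGeneric("locNames"))

#' Individual identifiers
#'
#' @param x a [GenotypePanel-class] object.
#' @return Character vector of individual ids.
#' @export
setGeneric("indNames", function(x) standardGeneric("indNames"))

#' Per-individual site labels
#'
#' @param x a [GenotypePanel-class] object.
#' @return Character vector, one site label per individual.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' Per-individual cluster labels
#'
#' @param x a [GenotypePanel-class] object.
#' @return Character vector, one cluster label per individual.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' Replace cluster labels
#'
#' @param x a [GenotypePanel-class] object.
#' @param value character vector of per-individual cluster labels, or a named
#'   character vector mapping site label -> cluster label.
#' @return The modified panel.
#' @export
setGeneric("clusters<-", function(x, value) standardGeneric("clusters<-"))

#' Genotypes as a three-dimensional array
#'
#' @param x a [GenotypePanel-class] object.
#' @return Integer array `individuals x loci x 2` of allele sizes (repeat
#'   counts); `NA` marks missing genotypes.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Posterior membership fractions of a clustering model
#'
#' @param x a [ClusterModel-class] object.
#' @return Numeric matrix `individuals x K`; rows sum to 1.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
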