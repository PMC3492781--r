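## Rank-based Mantel correlation between labeled square matrices,
## supporting asymmetric (directional) matrices, label-permutation nulls,
## one-tailed tests, and cluster exclusion.

offDiag <- function(m) m[row(m) != col(m)]

#' Rank-transform the off-diagonal cells of a square matrix
#'
#' Off-diagonal cells are replaced by mid-ranks (ties averaged); the
#' diagonal is untouched. For symmetric matrices both copies of each
#' unordered pair are ranked, so they receive equal ranks and symmetry is
#' preserved.
#'
#' @param m labeled square numeric matrix.
#' @return Matrix of the same shape with ranked off-diagonal cells.
#' @export
rankTransform <- function(m) {
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  off <- row(m) != col(m)
  v <- m[off]
  if (length(unique(v)) == 1L) {
    warning("all off-diagonal cells are equal; ranks are uninformative")
  }
  m[off] <- rank(v)
  m
}

## Align matrix b to a's labels; both must carry dimnames on both margins.
alignPair <- function(a, b) {
  la <- rownames(a)
  lb <- rownames(b)
  if (is.null(la) || is.null(lb)) stop("matrices must be labeled (dimnames)")
  if (!setequal(la, lb)) {
    stop(
      "label mismatch: only in first = {",
      paste(setdiff(la, lb), collapse = ", "), "}; only in second = {",
      paste(setdiff(lb, la), collapse = ", "), "}"
    )
  }
  b[la, la, drop = FALSE]
}

#' Rank-based Mantel test between two labeled square matrices
#'
#' Spearman correlation over the paired off-diagonal cells: both matrices
#' are mid-rank transformed and the Pearson correlation of the ranked cells
#' is taken. Asymmetric matrices are handled by using all `n(n-1)`
#' off-diagonal cells. The null distribution is generated by applying a
#' uniform random label permutation jointly to the rows and columns of the
#' second matrix. `P = (# permuted statistics at least as extreme + 1) /
#' (nPerm + 1)`.
#'
#' @param matA,matB labeled square numeric matrices over the same label set.
#' @param nPerm number of permutations (study convention: 9999).
#' @param tail `"greater"` (toward positive correlation), `"less"`, or
#'   `"two.sided"`.
#' @param seed optional RNG seed.
#' @param exclude labels to drop from both matrices before testing.
#' @param exact if `TRUE`, enumerate all label permutations instead of
#'   sampling (feasible for few labels); `P` is then the exact fraction of
#'   permutations, identity included, at least as extreme.
#' @return A [MantelResult-class].
#' @export
mantelRank <- function(matA, matB, nPerm = 9999L,
                       tail = c("greater", "less", "two.sided"),
                       seed = NULL, exclude = character(0), exact = FALSE) {
  tail <- match.arg(tail)
  matB <- alignPair(matA, matB)
  if (length(exclude)) {
    keep <- setdiff(rownames(matA), exclude)
    matA <- matA[keep, keep, drop = FALSE]
    matB <- matB[keep, keep, drop = FALSE]
  }
  n <- nrow(matA)
  if (n < 4L) stop("need at least 4 retained labels")
  ra <- rankTransform(matA)
  rb <- rankTransform(matB)
  x <- offDiag(ra)
  y <- offDiag(rb)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate rank vector: all off-diagonal cells tied")
  }
  if (!is.null(seed)) set.seed(seed)
  robs <- cor(x, y)
  stat <- function(perm) cor(x, offDiag(rb[perm, perm, drop = FALSE]))
  extreme <- function(r) {
    switch(tail,
      greater = r >= robs - 1e-12,
      less = r <= robs + 1e-12,
      two.sided = abs(r) >= abs(robs) - 1e-12
    )
  }
  if (exact) {
    perms <- permuteAll(n)
    stats <- vapply(perms, stat, 0)
    P <- mean(vapply(stats, extreme, TRUE))
    nP <- length(perms) - 1L
  } else {
    hits <- 0L
    for (b in seq_len(nPerm)) {
      if (extreme(stat(sample.int(n)))) hits <- hits + 1L
    }
    P <- (hits + 1) / (nPerm + 1)
    nP <- as.integer(nPerm)
  }
  new("MantelResult",
    pair = c(
      if (is.null(attr(matA, "name"))) "A" else attr(matA, "name"),
      if (is.null(attr(matB, "name"))) "B" else attr(matB, "name")
    ),
    R = robs, P = P, nPerm = nP, tail = tail,
    excluded = as.character(exclude), nLabels = n
  )
}

## All permutations of 1..n as a list (n small).
permuteAll <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- permuteAll(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      idx <- idx + 1L
      out[[idx]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Pairwise Mantel tests among several matrices
#'
#' Runs [mantelRank()] for every unordered pair of the named input matrices
#' and assembles the conventional combined table with correlation
#' coefficients above the diagonal and permutation p-values below. When
#' `exclude` is non-empty both the full and the excluded variants are
#' returned.
#'
#' @param matrices named list of labeled square matrices over a common
#'   label set.
#' @param nPerm,tail,seed passed to [mantelRank()] (each pair gets a
#'   deterministic sub-seed).
#' @param exclude labels to drop in the exclusion variant.
#' @return A list of class `MantelTable` with elements `table` (combined
#'   R/P matrix) and `results` (list of [MantelResult-class]); when
#'   `exclude` is non-empty, a list with elements `full` and `excluded`.
#' @export
correlationTable <- function(matrices, nPerm = 9999L,
                             tail = "greater", seed = NULL,
                             exclude = character(0)) {
  if (is.null(names(matrices)) || length(matrices) < 2L) {
    stop("need >= 2 named matrices")
  }
  if (length(exclude)) {
    return(list(
      full = correlationTable(matrices, nPerm, tail, seed),
      excluded = correlationTable(
        lapply(matrices, function(m) {
          keep <- setdiff(rownames(m), exclude)
          m[keep, keep, drop = FALSE]
        }),
        nPerm, tail, seed
      )
    ))
  }
  nms <- names(matrices)
  k <- length(nms)
  tab <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  results <- list()
  if (!is.null(seed)) set.seed(seed)
  pairSeeds <- sample.int(.Machine$integer.max, k * (k - 1) / 2)
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      idx <- idx + 1L
      a <- matrices[[i]]
      attr(a, "name") <- nms[i]
      b <- matrices[[j]]
      attr(b, "name") <- nms[j]
      res <- mantelRank(a, b,
        nPerm = nPerm, tail = tail,
        seed = if (is.null(seed)) NULL else pairSeeds[idx]
      )
      tab[i, j] <- res@R
      tab[j, i] <- res@P
      results[[paste(nms[i], nms[j], sep = "~")]] <- res
    }
  }
  structure(list(table = tab, results = results), class = "MantelTable")
}

#' @export
print.MantelTable <- function(x, ...) {
  cat("Mantel correlation table (R above diagonal, P below)\n")
  print(round(x$table, 4))
  invisible(x)
}
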